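test_that("ghd agrees with the brute-force definition", {
  # fixed 3-node pair evaluated by the loop oracle
  Wa <- ConnectivityMatrix(matrix(c(0, .2, .4, .2, 0, .6, .4, .6, 0), 3, 3,
                                  dimnames = list(letters[1:3], letters[1:3])))
  Wb <- ConnectivityMatrix(matrix(c(0, .6, .4, .6, 0, .2, .4, .2, 0), 3, 3,
                                  dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(ghd(Wa, Wb), oracle_ghd(weightMatrix(Wa), weightMatrix(Wb)))
  expect_equal(ghd(Wa, Wb), ghd(Wb, Wa))
  expect_equal(ghd(Wa, Wa), 0)

  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(6:15, 1))
    A <- rand_weights(n, seed)
    B <- rand_weights(n, seed + 50)
    expect_equal(ghd(A, B), oracle_ghd(weightMatrix(A), weightMatrix(B)),
                 tolerance = 1e-12)
    expect_gte(ghd(A, B), 0)
  }
})

test_that("closed-form null moments match the Monte-Carlo permutation oracle", {
  for (seed in 1:3) {
    A <- rand_weights(15, seed)
    B <- rand_weights(15, seed + 50)
    mom <- nullMoments(A, B)
    mc <- oracle_mc_null(weightMatrix(A), weightMatrix(B),
                         n_perm = 20000, seed = seed + 900)
    expect_lt(abs(mom$mu_pi - mc$mean), 3 * mc$se_mean)
    expect_lt(abs(mom$sigma2_pi - mc$var), 0.1 * mc$var)
  }
})

test_that("null moments are invariant under relabeling one network", {
  A <- rand_weights(12, 4)
  B <- rand_weights(12, 44)
  mom <- nullMoments(A, B)
  perm <- withr::with_seed(5, sample.int(12))
  Ap <- ConnectivityMatrix(weightMatrix(A)[perm, perm],
                           labels = nodeLabels(A))
  momp <- nullMoments(Ap, B)
  expect_equal(momp$mu_pi, mom$mu_pi, tolerance = 1e-12)
  expect_equal(momp$sigma2_pi, mom$sigma2_pi, tolerance = 1e-12)

  # joint relabeling leaves ghd and the moments unchanged
  Bp <- ConnectivityMatrix(weightMatrix(B)[perm, perm],
                           labels = nodeLabels(B))
  expect_equal(ghd(Ap, Bp), ghd(A, B), tolerance = 1e-12)
  expect_equal(nullMoments(Ap, Bp)$sigma2_pi, mom$sigma2_pi,
               tolerance = 1e-12)
})

test_that("constant weights give a degenerate null handled explicitly", {
  labs <- letters[1:6]
  cm <- matrix(0.3, 6, 6, dimnames = list(labs, labs)); diag(cm) <- 0
  A <- ConnectivityMatrix(cm)
  expect_equal(ghd(A, A), 0)
  mom <- nullMoments(A, A)
  expect_equal(mom$mu_pi, 0)
  expect_equal(mom$sigma2_pi, 0)
  expect_warning(tst <- ghdTest(A, A), "degenerate")
  expect_equal(tst@pValue, 1)
})

test_that("ghdTest standardizes consistently and detects dependence", {
  pr <- rand_conn_pair(60, 0.25, 12, seed = 9)
  tst <- ghdTest(pr$Wa, pr$Wb)
  mom <- nullMoments(pr$Wa, pr$Wb)
  expect_equal(tst@z, (ghd(pr$Wa, pr$Wb) - mom$mu_pi) / sqrt(mom$sigma2_pi))
  expect_equal(tst@pValue, stats::pnorm(tst@z))
  # a graph against itself is maximally dependent
  self <- ghdTest(pr$Wa, pr$Wa)
  expect_lt(self@z, -5)
  expect_lt(self@pValue, 1e-6)
})

test_that("node contributions decompose GHD and mu exactly", {
  # 4-node pair against the term-by-term loop oracle
  A <- rand_weights(4, 21)
  B <- rand_weights(4, 71)
  nc <- nodeContributions(A, B)
  orc <- oracle_contributions(weightMatrix(A), weightMatrix(B))
  expect_equal(nc$ghd_i, orc$ghd_i, tolerance = 1e-12)
  expect_equal(nc$mu_i, orc$mu_i, tolerance = 1e-12)

  # conservation on random instances
  for (seed in 1:6) {
    n <- withr::with_seed(seed + 30, sample(5:25, 1))
    A <- rand_weights(n, seed + 200)
    B <- rand_weights(n, seed + 250)
    nc <- nodeContributions(A, B)
    expect_equal(sum(nc$ghd_i), ghd(A, B), tolerance = 1e-9)
    expect_equal(sum(nc$mu_i), nullMoments(A, B)$mu_pi, tolerance = 1e-9)
  }

  # identical networks contribute nothing to the distance share
  same <- nodeContributions(A, A)
  expect_equal(same$ghd_i, rep(0, nrow(same)))
})

test_that("restrictNodes sub-selects weights without recomputation", {
  A <- rand_weights(8, 31)
  expect_equal(weightMatrix(restrictNodes(A, nodeLabels(A))),
               weightMatrix(A))
  two <- restrictNodes(A, c("v02", "v05"))
  expect_equal(weightMatrix(two)["v02", "v05"],
               weightMatrix(A)["v02", "v05"])
  expect_error(restrictNodes(A, character(0)), "non-empty")
  expect_error(restrictNodes(A, "nope"), "unknown")

  # restrict-then-ghd equals the brute-force value on the sub-matrix
  B <- rand_weights(8, 81)
  keep <- c("v01", "v03", "v04", "v07", "v08")
  expect_equal(ghd(restrictNodes(A, keep), restrictNodes(B, keep)),
               oracle_ghd(weightMatrix(A)[keep, keep],
                          weightMatrix(B)[keep, keep]),
               tolerance = 1e-12)
})

test_that("small-N guards match the moment formulas' domain", {
  A <- rand_weights(3, 1)
  B <- rand_weights(3, 2)
  expect_error(nullMoments(A, B), "at least 4")
  expect_error(ghdTest(A, B), "at least 4")
  one <- ConnectivityMatrix(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_error(ghd(one, one), "at least 2")
})
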