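test_that("identical networks show no differential signal beyond the small-n floor", {
  # Any sub-network of min_size-ish nodes carries too little information for
  # the normal approximation, so the terminal removals of even an identical
  # pair drift to p near 1; the substantive claim is that no call occurs
  # outside that terminal tail.
  g <- randomGeometric(250, 0.15, seed = 2)
  W <- cosineConnectivity(g)
  for (fun in list(closedForm, fastApproximation,
                   function(a, b) dghdBaseline(a, b))) {
    res <- fun(W, W)
    tab <- resultTable(res)
    called <- callDifferential(res)
    expect_lte(length(called), 10)
    expect_gte(min(tab$removal_order[tab$node %in% called]),
               max(tab$removal_order) - 10L)
  }
  # while the remaining sub-network is large, dependence stays overwhelming
  cf <- closedForm(W, W)
  tr <- removalTrace(cf)
  expect_true(all(tr$p[tr$remaining_n > 30] <= 1e-50))
})

test_that("the removal trace is consistent and reproducible step by step", {
  pr <- rand_conn_pair(50, 0.25, 10, seed = 13)
  res <- closedForm(pr$Wa, pr$Wb)
  tr <- removalTrace(res)
  expect_equal(tr$remaining_n, seq(50, by = -1, length.out = nrow(tr)))
  expect_true(all(tr$p >= 0 & tr$p <= 1))

  # every trace row reproduces a direct ghdTest on the restricted matrices
  tab <- resultTable(res)
  removed <- tab$node[tab$phase != "survivor"]
  for (step in c(10, 30, nrow(tr) - 1)) {
    keep <- setdiff(pr$universe, removed[seq_len(step)])
    td <- ghdTest(restrictNodes(pr$Wa, keep), restrictNodes(pr$Wb, keep))
    expect_equal(tr$ghd[step + 1], td@ghd, tolerance = 1e-9)
    expect_equal(tr$mu_pi[step + 1], td@muPi, tolerance = 1e-9)
    expect_equal(tr$sigma_pi[step + 1], td@sigmaPi, tolerance = 1e-9)
  }

  # phase 2 never precedes phase 1; p assignment follows removal order
  ph <- tab$phase[tab$phase != "survivor"]
  expect_true(all(diff(match(ph, c("1", "2"))) >= 0))
  expect_equal(tab$p_value[seq_along(removed)], tr$p[-1])
})

test_that("phase-2 removals match an exhaustive brute-force search", {
  # toy pair whose full-network p is large, so phase 2 starts immediately
  A <- rand_weights(6, 5)
  B <- rand_weights(6, 55)
  expect_gt(ghdTest(A, B)@pValue, 1e-50)  # independent weights
  res <- closedForm(A, B, min_size = 4)
  tab <- resultTable(res)
  expect_true(all(tab$phase[tab$phase != "survivor"] == "2"))

  # exhaustive oracle: at each step remove the argmax of brute-force cGHD
  Am <- weightMatrix(A); Bm <- weightMatrix(B)
  labs <- nodeLabels(A)
  alive <- labs
  expected <- character(0)
  while (length(alive) > 4) {
    vals <- vapply(alive, function(v) {
      keep <- setdiff(alive, v)
      oracle_cghd(Am[keep, keep], Bm[keep, keep])
    }, 0)
    pick <- alive[which.max(vals)]
    expected <- c(expected, pick)
    alive <- setdiff(alive, pick)
  }
  expect_identical(tab$node[seq_along(expected)], expected)
})

test_that("fast approximation's leave-one-out scores match brute force", {
  A <- rand_weights(5, 61)
  B <- rand_weights(5, 62)
  st <- ghdiff:::.engine_init(A, B)
  cand <- ghdiff:::.engine_candidates(st)
  expect_equal(unname(cand),
               oracle_loo_cghd(weightMatrix(A), weightMatrix(B)),
               tolerance = 1e-12)
})

test_that("closed-form and fast approximation give identical removal orders", {
  for (seed in 1:6) {
    pr <- rand_conn_pair(100, 0.2, 20, seed = 3000 + seed)
    cf <- closedForm(pr$Wa, pr$Wb)
    fa <- fastApproximation(pr$Wa, pr$Wb)
    expect_identical(resultTable(cf)$node, resultTable(fa)$node)
    expect_identical(callDifferential(cf), callDifferential(fa))
  }
})

test_that("the dGHD baseline removes the largest absolute cGHD share first", {
  A <- rand_weights(5, 91)
  B <- rand_weights(5, 92)
  res <- dghdBaseline(A, B)
  orc <- oracle_contributions(weightMatrix(A), weightMatrix(B))
  first <- nodeLabels(A)[which.max(abs(orc$contribution))]
  expect_identical(resultTable(res)$node[1], first)
})

test_that("BH adjustment matches the step-up formula and validates input", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFdr(0.2), 0.2)
  expect_equal(adjustFdr(rep(0.37, 5)), rep(0.37, 5))
  expect_error(adjustFdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("differential calling thresholds the adjusted p-values", {
  pr <- rand_conn_pair(40, 0.3, 8, seed = 77)
  res <- closedForm(pr$Wa, pr$Wb)
  tab <- resultTable(res)
  expect_setequal(callDifferential(res), tab$node[tab$p_adjusted > 0.01])
  expect_setequal(callDifferential(res, alpha = 0.5),
                  tab$node[tab$p_adjusted > 0.5])
  expect_true(all(tab$p_adjusted >= tab$p_value))
})

test_that("parameter guards reject invalid settings", {
  pr <- rand_conn_pair(20, 0.3, 4, seed = 6)
  expect_error(closedForm(pr$Wa, pr$Wb, theta = 0), "theta")
  expect_error(closedForm(pr$Wa, pr$Wb, theta = 1), "theta")
  expect_error(closedForm(pr$Wa, pr$Wb, min_size = 3), "min_size")
  small <- rand_weights(4, 2)
  expect_error(closedForm(small, small, min_size = 10), "min_size")
})
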