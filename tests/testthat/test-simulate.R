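test_that("random geometric graphs are deterministic and well-formed", {
  g1 <- randomGeometric(100, 0.15, seed = 5)
  g2 <- randomGeometric(100, 0.15, seed = 5)
  g3 <- randomGeometric(100, 0.15, seed = 6)
  expect_identical(adjacency(g1), adjacency(g2))
  expect_false(identical(adjacency(g1), adjacency(g3)))
  expect_true(all(adjacency(g1) %in% c(0, 1)))
  # canonical label order equals generation order
  expect_identical(nodeLabels(g1), sort(nodeLabels(g1)))
  expect_error(randomGeometric(100, 1.5, seed = 1), "sqrt\\(2\\)")
})

test_that("RG edge counts match the closed-form distance probability", {
  # P(dist < d) for uniform points on the unit square
  d <- 0.15
  p_d <- pi * d^2 - (8 / 3) * d^3 + d^4 / 2
  n <- 100
  counts <- vapply(1:200, function(s)
    sum(adjacency(randomGeometric(n, d, seed = 5000 + s))) / 2, 0)
  expected <- choose(n, 2) * p_d
  se <- sqrt(choose(n, 2) * p_d * (1 - p_d) / 200)  # conservative SE
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("permuting the first k indices relabels without changing structure", {
  g <- randomGeometric(60, 0.25, seed = 8)
  gp <- permuteFirstK(g, 20, seed = 9)
  expect_identical(nodeLabels(gp), nodeLabels(g))
  # degree multiset preserved, untouched block identical
  expect_equal(unname(sort(rowSums(adjacency(gp)))), unname(sort(rowSums(adjacency(g)))))
  expect_identical(adjacency(gp)[21:60, 21:60], adjacency(g)[21:60, 21:60])

  # a seed whose uniform permutation of 1..2 is the identity leaves g intact
  id_seed <- Find(function(s) identical(withr::with_seed(s, sample.int(2)),
                                        1:2), 1:50)
  expect_identical(adjacency(permuteFirstK(g, 2, seed = id_seed)),
                   adjacency(g))
  expect_error(permuteFirstK(g, 1, seed = 1), "k must")
})

test_that("dense-block replacement is local by default and denser on average", {
  g <- randomGeometric(80, 0.15, seed = 12)
  gb <- replaceDenseSubnetwork(g, 20, 0.5, seed = 13)
  expect_identical(adjacency(gb)[21:80, 21:80], adjacency(g)[21:80, 21:80])
  expect_identical(adjacency(gb)[1:20, 21:80], adjacency(g)[1:20, 21:80])

  # with d' > d the expected edge count inside the block increases
  inner <- function(gr) sum(adjacency(gr)[1:20, 1:20]) / 2
  before <- after <- numeric(50)
  for (s in 1:50) {
    ga <- randomGeometric(80, 0.15, seed = 6000 + s)
    before[s] <- inner(ga)
    after[s] <- inner(replaceDenseSubnetwork(ga, 20, 0.5, seed = 7000 + s))
  }
  expect_gt(mean(after), mean(before))

  # replace_incident drops the crossing edges of the planted nodes
  gi <- replaceDenseSubnetwork(g, 20, 0.5, seed = 13, replace_incident = TRUE)
  expect_equal(sum(adjacency(gi)[1:20, 21:80]), 0)
  expect_identical(adjacency(gi)[21:80, 21:80], adjacency(g)[21:80, 21:80])

  # k = N: an entirely fresh graph
  gfull <- replaceDenseSubnetwork(g, 80, 0.5, seed = 14)
  expect_identical(nodeLabels(gfull), nodeLabels(g))
  expect_true(validObject(gfull))
})

test_that("power-law graphs hit the requested edge count and tail exponent", {
  g <- powerLaw(1000, 10000, gamma = 3, seed = 17)
  m <- adjacency(g)
  expect_equal(sum(m) / 2, 10000)
  expect_true(all(diag(m) == 0))
  expect_true(all(m %in% c(0, 1)))

  # ML (Hill) estimate of the tail exponent over degrees >= 10
  deg <- rowSums(m)
  tail <- deg[deg >= 10]
  xmin <- 10
  alpha_hat <- 1 + length(tail) / sum(log(tail / (xmin - 0.5)))
  expect_lt(abs(alpha_hat - 3), 0.5)

  # near-uniform weights: degrees concentrate like an Erdos-Renyi graph
  ger <- powerLaw(500, 2000, gamma = 1000, seed = 18)
  dg <- rowSums(adjacency(ger))
  expect_lt(max(dg), 3 * mean(dg))
  expect_error(powerLaw(10, 100, gamma = 3, seed = 1), "n\\(n-1\\)/2")
})

test_that("benchmark instances are deterministic with the advertised gold set", {
  spec <- simulationSpec("rg_permuted", N = 250, d = 0.15, k = 50, seed = 7)
  inst <- makeInstance(spec)
  expect_length(inst$gold, 50)
  expect_identical(inst$gold, nodeLabels(inst$graph_a)[1:50])
  inst2 <- makeInstance(spec)
  expect_identical(adjacency(inst$graph_b), adjacency(inst2$graph_b))

  dn <- makeInstance(simulationSpec("rg_denser", N = 200, d = 0.3, k = 40,
                                    d_prime = 0.5, seed = 3))
  blk <- function(g) sum(adjacency(g)[1:40, 1:40]) / 2
  expect_gt(blk(dn$graph_b), blk(dn$graph_a))

  pl <- makeInstance(simulationSpec("pl_permuted", N = 300, k = 50, E = 1500,
                                    gamma = 2, seed = 4))
  expect_equal(unname(sort(rowSums(adjacency(pl$graph_b)))),
               unname(sort(rowSums(adjacency(pl$graph_a)))))

  expect_error(simulationSpec("rg_denser", N = 100, d = 0.3, k = 10,
                              d_prime = 0.2, seed = 1), "d_prime")
  expect_error(simulationSpec("rg_permuted", N = 10, d = 0.3, k = 10,
                              seed = 1), "k must")
})
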