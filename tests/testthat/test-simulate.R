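test_that("random trees have 2n-3 edges, exponential lengths, and are reproducible", {
  expect_error(randomTree(1, seed = 1), ">= 2")
  tr5 <- randomTree(5, seed = 1)
  expect_identical(nrow(tr5$edge), 7L)
  expect_identical(ape::write.tree(randomTree(5, seed = 1)), ape::write.tree(tr5))
  expect_false(identical(ape::write.tree(randomTree(5, seed = 2)),
                         ape::write.tree(tr5)))
  # pooled branch lengths match the exponential mean within 2%
  lens <- unlist(lapply(1:600, function(s)
    randomTree(10, seed = s, meanBranchLength = 0.1)$edge.length))
  expect_gt(length(lens), 10000)
  expect_lt(abs(mean(lens) - 0.1) / 0.1, 0.02)
})

test_that("zero branch lengths copy the root draw to every taxon", {
  tr <- randomTree(6, seed = 2)
  tr$edge.length[] <- 0
  aln <- simulateAlignment(tr, srAssignment(), rho = 0.5, nSites = 25, seed = 4)
  expect_identical(nTaxa(aln), 6L)
  expect_identical(nSites(aln), 25L)
  for (i in 2:6) expect_identical(aln@states[i, ], aln@states[1, ])
})

test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  tr <- randomTree(5, seed = 3, meanBranchLength = 0.2)
  set.seed(123); before <- .Random.seed
  a1 <- simulateAlignment(tr, randomAssignment(2, seed = 5), rho = c(0.2, 2),
                          nSites = 50, seed = 9)
  expect_identical(.Random.seed, before)
  a2 <- simulateAlignment(tr, randomAssignment(2, seed = 5), rho = c(0.2, 2),
                          nSites = 50, seed = 9)
  expect_identical(a1@states, a2@states)
  a3 <- simulateAlignment(tr, randomAssignment(2, seed = 5), rho = c(0.2, 2),
                          nSites = 50, seed = 10)
  expect_false(identical(a1@states, a3@states))
  # ground truth travels with the alignment
  expect_identical(a1@metadata$truth$rho, c(0.2, 2))
})

test_that("long-branch simulations converge to the stationary distribution", {
  tr <- ape::read.tree(text = "(a:10,b:10);")
  prm <- randomModelParams(seed = 31)
  aln <- simulateAlignment(tr, srAssignment(), rho = 0.5, theta = prm$theta,
                           pi = prm$pi, nSites = 50000, seed = 6)
  p <- stationaryDistribution(prm$pi)
  emp <- tabulate(aln@states, 61) / (2 * 50000)
  tv <- sum(abs(emp - p)) / 2
  expect_lt(tv, 0.01)
})

test_that("Gillespie event logs match expected substitution flows", {
  tr <- ape::read.tree(text = "(a:0.4,b:0.4);")
  a <- srAssignment()
  aln <- simulateAlignment(tr, a, rho = 0.3, nSites = 1500, seed = 7,
                           logEvents = TRUE)
  ev <- aln@metadata$events
  expect_true(all(c("edge", "site", "time", "from", "to", "synonymous") %in%
                    names(ev)))
  m <- codonRateMatrix(a, rho = 0.3)
  p <- stationary(m)
  ev61 <- oneStepEvents()
  flow <- p[ev61$fromState] * m@Q[cbind(ev61$fromState, ev61$toState)]
  tTot <- sum(tr$edge.length) * 1500
  expSyn <- sum(flow[ev61$synonymous]) * tTot
  expNonsyn <- sum(flow[!ev61$synonymous]) * tTot
  obsSyn <- sum(ev$synonymous)
  obsNonsyn <- sum(!ev$synonymous)
  expect_lt(abs(obsSyn - expSyn), 4 * sqrt(expSyn))
  expect_lt(abs(obsNonsyn - expNonsyn), 4 * sqrt(expNonsyn))
})
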