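test_that("a single taxon needs no tree and sums log stationary frequencies", {
  prm <- randomModelParams(seed = 21)
  m <- codonRateMatrix(srAssignment(), 0.5, prm$theta, prm$pi)
  aln <- randomStatesAlignment("only", 40, missingProb = 0.2, seed = 3)
  st <- aln@states[1, ]
  expect_equal(codonLogLik(NULL, aln, m),
               sum(log(stationary(m)[st[!is.na(st)]])))
})

test_that("pruning equals exhaustive summation on a 3-taxon tree with missing data", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.4,C:0.25);")
  prm <- randomModelParams(K = 2, seed = 11)
  m <- codonRateMatrix(randomAssignment(2, seed = 11), prm$rho[1:2],
                       prm$theta, prm$pi)
  aln <- randomStatesAlignment(c("A", "B", "C"), 6, missingProb = 0.25, seed = 12)
  expect_equal(codonLogLik(tr, aln, m), bruteForceLogLik(tr, aln, m),
               tolerance = 1e-10)
})

test_that("duplicated columns double the log-likelihood (pattern compression)", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,C:0.3,D:0.15);")
  prm <- randomModelParams(seed = 13)
  m <- codonRateMatrix(srAssignment(), 0.4, prm$theta, prm$pi)
  aln <- randomStatesAlignment(c("A", "B", "C", "D"), 30, seed = 14)
  ll <- codonLogLik(tr, aln, m)
  dup <- methods::new("CodonAlignment",
                      states = cbind(aln@states, aln@states),
                      stateSpace = aln@stateSpace, metadata = list())
  expect_equal(codonLogLik(tr, dup, m), 2 * ll, tolerance = 1e-9)
})

test_that("the likelihood is invariant to re-rooting (time reversibility)", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.12,(C:0.3,D:0.15):0.08,E:0.2);")
  prm <- randomModelParams(seed = 15)
  m <- codonRateMatrix(srAssignment(), 0.6, prm$theta, prm$pi)
  aln <- randomStatesAlignment(c("A", "B", "C", "D", "E"), 50, seed = 16)
  ll <- codonLogLik(tr, aln, m)
  for (og in c("A", "C", "E")) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(codonLogLik(rerooted, aln, m), ll, tolerance = 1e-8)
  }
})

test_that("deep trees engage partial-likelihood rescaling without changing results", {
  # a caterpillar tree large enough to trigger the rescaled code path
  set.seed(17)
  tr <- ape::rtree(40)
  tr$edge.length <- rexp(nrow(tr$edge), 10)
  prm <- randomModelParams(seed = 17)
  m <- codonRateMatrix(srAssignment(), 0.5, prm$theta, prm$pi)
  aln <- randomStatesAlignment(tr$tip.label, 20, seed = 18)
  ll <- codonLogLik(tr, aln, m)
  expect_true(is.finite(ll))
  # the rescaled pass must agree with the plain pass (still within
  # double range at 40 taxa)
  pp <- codonbench:::.preparePruning(tr, aln)
  expect_true(pp$rescale)
  pp$rescale <- FALSE
  llPlain <- codonbench:::.pruneLogLik(pp, codonbench:::eigenSystem(m),
                                       pp$tree$edge.length)
  expect_equal(ll, llPlain, tolerance = 1e-8)
})

test_that("taxon mismatches and invalid trees are rejected", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);")
  prm <- randomModelParams(seed = 19)
  m <- codonRateMatrix(srAssignment(), 0.5, prm$theta, prm$pi)
  aln <- randomStatesAlignment(c("A", "B", "X"), 5, seed = 20)
  expect_error(codonLogLik(tr, aln, m), "mismatch")
  aln2 <- randomStatesAlignment(c("A", "B"), 5, seed = 20)
  expect_error(codonLogLik(NULL, aln2, m), "tree is required")
})
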