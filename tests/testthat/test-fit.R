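test_that("free-parameter accounting follows the branch/bias/frequency/class rule", {
  tr13 <- randomTree(13, seed = 130)
  cnt <- countFreeParameters(srAssignment(), tr13)
  expect_identical(cnt$branches, 23L)  # 2 * 13 - 3
  expect_identical(cnt$total, 38L)     # 23 + 5 + 9 + 1
  expect_identical(cnt$rateParameters, 1L)
  expect_identical(countFreeParameters(revAssignment(), tr13)$rateParameters, 75L)
  # observed frequencies / HKY-like biases reduce the count
  expect_identical(countFreeParameters(srAssignment(), tr13,
                                       freqPolicy = "observed")$total, 29L)
  expect_identical(countFreeParameters(srAssignment(), tr13,
                                       biasModel = "hky")$total, 34L)
  # an empty class contributes no estimable rate
  cl <- classOf(srAssignment())
  cl[] <- rep(c(1L, 2L, 4L, 5L), length.out = 75)  # class 3 empty
  asn <- rateClassAssignment(cl, nClasses = 5L)
  expect_identical(countFreeParameters(asn, tr13)$rateParameters, 4L)
})

test_that("omega is recovered on data simulated under SR", {
  tr <- randomTree(8, seed = 101, meanBranchLength = 0.25)
  aln <- simulateAlignment(tr, srAssignment(), rho = 0.3, nSites = 2000,
                           seed = 102)
  fit <- fitCodonModel(tr, aln, srAssignment())
  expect_true(fit@converged)
  expect_lt(abs(fit@estimates$rho - 0.3), 0.05)
  # fitted branch lengths stay in a sane range
  expect_true(all(fit@estimates$branchLengths > 0))
})

test_that("refining the class partition never lowers the optimized likelihood", {
  tr <- randomTree(6, seed = 103, meanBranchLength = 0.2)
  trueA <- randomAssignment(3, seed = 104)
  aln <- simulateAlignment(tr, trueA, rho = c(0.2, 1, 3), nSites = 200,
                           seed = 105)
  fsr <- fitCodonModel(tr, aln, srAssignment())
  f3 <- fitCodonModel(tr, aln, trueA, start = fsr)
  frev <- fitCodonModel(tr, aln, revAssignment(), start = f3,
                        updateBlocks = c("branch", "rates"))
  expect_gte(f3@logLik, fsr@logLik - 1e-6)
  expect_gte(frev@logLik, f3@logLik - 1e-6)
  # the warm start expands nested parameters, so the initial point of
  # each refit already reproduces the parent model
  expect_gte(f3@logLik, fsr@logLik)
})

test_that("invariant alignments converge to the boundary and are flagged", {
  tr <- randomTree(4, seed = 110, meanBranchLength = 0.2)
  states <- matrix(5L, 4, 30, dimnames = list(tr$tip.label, NULL))
  aln <- methods::new("CodonAlignment", states = states,
                      stateSpace = senseCodonSpace(geneticCode()),
                      metadata = list())
  fit <- fitCodonModel(tr, aln, srAssignment(), control = list(maxOuter = 6L))
  expect_true(fit@converged)
  expect_true(fit@boundary)
  expect_true(all(fit@estimates$branchLengths <= 1e-8))
})

test_that("an exhausted iteration budget is reported as non-convergence", {
  tr <- randomTree(6, seed = 140, meanBranchLength = 0.3)
  aln <- simulateAlignment(tr, randomAssignment(2, seed = 141), rho = c(0.1, 5),
                           nSites = 150, seed = 142)
  fit <- fitCodonModel(tr, aln, randomAssignment(2, seed = 141),
                       control = list(maxOuter = 1L, innerMaxit = 2L))
  expect_false(fit@converged)
  expect_true(is.finite(fit@logLik))
})

test_that("rate estimation error shrinks as alignments grow", {
  trueA <- randomAssignment(2, seed = 120)
  tr <- randomTree(6, seed = 121, meanBranchLength = 0.3)
  relErr <- function(n) {
    aln <- simulateAlignment(tr, trueA, rho = c(0.2, 2), nSites = n, seed = 122)
    fit <- fitCodonModel(tr, aln, trueA)
    max(abs(fit@estimates$rho - c(0.2, 2)) / c(0.2, 2))
  }
  eSmall <- relErr(200)
  eLarge <- relErr(2000)
  expect_lt(eLarge, eSmall)
  expect_lt(eLarge, 0.25)
})

test_that("fixed branch lengths and observed frequencies are honoured", {
  tr <- randomTree(5, seed = 150, meanBranchLength = 0.2)
  aln <- simulateAlignment(tr, srAssignment(), rho = 0.5, nSites = 150,
                           seed = 151)
  fit <- fitCodonModel(tr, aln, srAssignment(), freqPolicy = "observed",
                       updateBlocks = c("frequencies", "rates"),
                       control = list(maxOuter = 5L))
  expect_equal(ape::reorder.phylo(fit@tree, "postorder")$edge.length,
               ape::reorder.phylo(tr, "postorder")$edge.length)
  expect_equal(fit@estimates$pi, observedPositionalFreqs(aln),
               tolerance = 1e-12)
  expect_identical(fit@nFreeParameters,
                   as.integer(countFreeParameters(srAssignment(), tr,
                                                  freqPolicy = "observed")$total))
})
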