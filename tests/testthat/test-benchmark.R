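# minimal fit objects for closed-form tests of the comparison machinery
makeFit <- function(logLik, nFree, assignment, rates = effectiveClasses(assignment),
                    converged = TRUE) {
  methods::new("FitResult", logLik = logLik, estimates = list(),
               nFreeParameters = as.integer(nFree),
               rateParameterCount = as.integer(rates),
               converged = converged, boundary = FALSE,
               modelDescriptor = list(assignment = assignment),
               tree = NULL, seed = NA_real_)
}

test_that("the likelihood-ratio test matches the chi-square closed form", {
  sr <- srAssignment()
  a5 <- randomAssignment(5, seed = 160)  # all classes occupied
  expect_identical(effectiveClasses(a5), 5L)
  null <- makeFit(-1000, 30, sr)
  # equal log-likelihoods: statistic 0, p = 1
  alt0 <- makeFit(-1000, 34, a5)
  cmp0 <- lrTest(null, alt0)
  expect_identical(cmp0@lrStatistic, 0)
  expect_identical(cmp0@pValue, 1)
  expect_identical(cmp0@df, 4L)  # K - 1 under shared policies
  # the 5% critical value of chi-square(1)
  alt1 <- makeFit(-1000 + 3.841 / 2, 31, randomAssignment(2, seed = 161))
  cmp1 <- lrTest(null, alt1)
  expect_equal(cmp1@pValue, pchisq(3.841, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(cmp1@pValue, 0.0500, tolerance = 1e-3)
  # tiny negative statistics are optimizer noise, clamped to zero
  altNeg <- makeFit(-1000 - 1e-8, 34, a5)
  expect_identical(lrTest(null, altNeg)@lrStatistic, 0)
  # grossly negative ones are an inconsistency
  expect_error(lrTest(null, makeFit(-1010, 34, a5)), "lower likelihood")
  # non-nested models are refused
  expect_error(lrTest(makeFit(-990, 34, a5), null), "not nested")
})

test_that("Bonferroni correction divides alpha by the number of tests", {
  null <- makeFit(-1000, 30, srAssignment())
  a2 <- randomAssignment(2, seed = 162)
  # p ~ 0.01: raw-significant at 0.05, not at 0.05/100
  alt <- makeFit(-1000 + qchisq(0.99, 1) / 2, 31, a2)
  cmp <- lrTest(null, alt, alpha = 0.05, bonferroniN = 100)
  expect_true(cmp@significantRaw)
  expect_false(cmp@significantBonferroni)
  expect_equal(cmp@bonferroniAlpha, 5e-4)
})

test_that("BIC follows -2LL + p log(n)", {
  f <- makeFit(-100, 10, srAssignment())
  expect_equal(bic(f, 100), 200 + 10 * log(100), tolerance = 1e-12)
  expect_equal(bic(f, 100), 246.0517, tolerance = 1e-4)
  # one more parameter with no likelihood gain costs exactly log(n)
  f2 <- makeFit(-100, 11, srAssignment())
  expect_equal(bic(f2, 100) - bic(f, 100), log(100), tolerance = 1e-12)
  expect_error(bic(f, 0), ">= 1")
})

test_that("BIC prefers the true 2-class model over SR and REV on strong data", {
  trueA <- randomAssignment(2, seed = 170)
  tr <- randomTree(8, seed = 171, meanBranchLength = 0.25)
  aln <- simulateAlignment(tr, trueA, rho = c(0.1, 3), nSites = 1000, seed = 172)
  n <- nSites(aln)
  fsr <- fitCodonModel(tr, aln, srAssignment())
  f2 <- fitCodonModel(tr, aln, trueA, start = fsr)
  frev <- fitCodonModel(tr, aln, revAssignment(), start = f2,
                        updateBlocks = c("branch", "rates"))
  expect_lt(bic(f2, n), bic(fsr, n))
  expect_lt(bic(f2, n), bic(frev, n))
})

test_that("ensembles are reproducible and respect the significance ordering", {
  tr <- randomTree(5, seed = 180, meanBranchLength = 0.25)
  aln <- simulateAlignment(tr, randomAssignment(2, seed = 181), rho = c(0.2, 2),
                           nSites = 200, seed = 182)
  e1 <- runRandomEnsemble(aln, tr, K = 2, nReplicates = 4, baseSeed = 90)
  e2 <- runRandomEnsemble(aln, tr, K = 2, nReplicates = 4, baseSeed = 90)
  expect_equal(e1@meanBic, e2@meanBic, tolerance = 1e-12)
  expect_identical(sapply(e1@fits, slot, "logLik"),
                   sapply(e2@fits, slot, "logLik"))
  expect_identical(e1@seeds, 90 + 0:3)
  expect_lte(e1@nSignificantBonferroni, e1@nSignificantRaw)
  for (cmp in e1@comparisons) {
    expect_gte(cmp@lrStatistic, 0)
    if (cmp@significantBonferroni) expect_true(cmp@significantRaw)
  }
})

test_that("null LR statistics track chi-square(K-1) (QQ slope near 1)", {
  tr <- randomTree(6, seed = 601, meanBranchLength = 0.25)
  aln <- simulateAlignment(tr, srAssignment(), rho = 0.5, nSites = 300,
                           seed = 602)
  ens <- runRandomEnsemble(aln, tr, K = 2, nReplicates = 200, baseSeed = 701)
  expect_identical(ens@nNonConverged, 0L)
  stats <- vapply(ens@comparisons, slot, numeric(1), "lrStatistic")
  qe <- quantile(stats, (1:19) / 20)
  qt <- qchisq((1:19) / 20, df = 1)
  slope <- sum(qe * qt) / sum(qt^2)
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("benchmark tables render counts as 'raw (bonferroni)' and flag best BIC", {
  sr <- makeFit(-10000, 38, srAssignment())
  ens <- methods::new("EnsembleResult", K = 2L, nReplicates = 100L,
                      seeds = as.numeric(1:100), srFit = sr, fits = list(),
                      comparisons = list(), nSignificantRaw = 43L,
                      nSignificantBonferroni = 15L, nNonConverged = 0L,
                      meanBic = 20970.3, alpha = 0.05, nSites = 277L)
  entries <- list(PF00803 = list(nTaxa = 13L, nSites = 277L,
                                 ensembles = list(ens),
                                 fits = list(REV = makeFit(-10100, 112,
                                                           revAssignment()))))
  tabs <- summarizeBenchmark(entries)
  expect_identical(tabs$significance$K2, "43 (15)")
  expect_identical(tabs$significance$N, 13L)
  expect_true(all(c("SR", "random K=2", "REV") %in% names(tabs$bicTable)))
  expect_identical(tabs$bicTable$best,
                   names(which.min(unlist(tabs$bicTable[1, c("SR", "random K=2", "REV")]))))
  # degenerate input: header-only tables
  empty <- summarizeBenchmark(list())
  expect_identical(nrow(empty$significance), 0L)
})
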