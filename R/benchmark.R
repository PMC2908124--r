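#' Likelihood-ratio test between nested fits
#'
#' Tests a null fit against an alternative whose rate-class partition
#' refines the null's (e.g. SR against any random-K model). The
#' statistic `2 * (LL_alt - LL_null)` is referred to a chi-square
#' distribution whose degrees of freedom equal the difference in free
#' parameters -- the difference in effective class counts when the two
#' fits share the remaining parameter policy (K - 1 for random-K
#' versus SR).
#'
#' @param nullFit,altFit [FitResult-class] objects on the same data;
#'   the null assignment must be nested in the alternative's.
#' @param alpha nominal significance level (default 0.05).
#' @param bonferroniN number of tests a Bonferroni correction should
#'   account for; `significantBonferroni` uses level
#'   `alpha / bonferroniN` (default 1, i.e. no correction).
#' @param tolerance negative statistics larger than `-tolerance` are
#'   clamped to zero (optimizer noise); more negative values are an
#'   error.
#' @return a [ModelComparison-class].
#' @examples
#' \dontrun{lrTest(srFit, randomFit, alpha = 0.05, bonferroniN = 100)}
#' @export
lrTest <- function(nullFit, altFit, alpha = 0.05, bonferroniN = 1L,
                   tolerance = 1e-6) {
  stopifnot(is(nullFit, "FitResult"), is(altFit, "FitResult"))
  a0 <- nullFit@modelDescriptor$assignment
  a1 <- altFit@modelDescriptor$assignment
  if (is.null(a0) || is.null(a1) || !isNestedAssignment(a0, a1))
    stop("null model is not nested in the alternative", call. = FALSE)
  df <- altFit@nFreeParameters - nullFit@nFreeParameters
  if (df < 1L)
    stop("nested test requires at least one extra free parameter", call. = FALSE)
  stat <- 2 * (altFit@logLik - nullFit@logLik)
  if (stat < -tolerance)
    stop("alternative fit has lower likelihood than the null (", stat,
         "); fits are inconsistent", call. = FALSE)
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  bAlpha <- alpha / bonferroniN
  new("ModelComparison", lrStatistic = stat, df = as.integer(df),
      pValue = p, alpha = alpha, bonferroniAlpha = bAlpha,
      significantRaw = p < alpha,
      significantBonferroni = p < bAlpha)
}

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison: LR = ", format(object@lrStatistic, digits = 6),
      ", df = ", object@df, ", p = ", format(object@pValue, digits = 4),
      if (object@significantRaw) " *",
      if (object@significantBonferroni) " (Bonferroni *)", "\n", sep = "")
})

#' Bayesian information criterion of a fit
#'
#' `BIC = -2 * LL + p * log(n)` with `p` the fit's free-parameter
#' count and `n` the sample size -- by convention here the number of
#' codon sites in the alignment. Smaller is better.
#'
#' @param fit a converged [FitResult-class].
#' @param n sample size, `>= 1` (codon sites).
#' @return numeric BIC.
#' @examples
#' \dontrun{bic(fit, n = nSites(aln))}
#' @export
bic <- function(fit, n) {
  stopifnot(is(fit, "FitResult"))
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("sample size n must be a single number >= 1", call. = FALSE)
  -2 * fit@logLik + fit@nFreeParameters * log(n)
}

#' Fit an ensemble of random rate-class models
#'
#' The random-model benchmarking protocol: fit the SR model once, then
#' fit `nReplicates` models whose 75 one-step residue pairs are
#' assigned independently and uniformly at random to `K` classes
#' (assignment seeds `baseSeed, baseSeed + 1, ...`), each warm-started
#' from the SR optimum so the nesting inequality holds by
#' construction. Each replicate is compared to SR with a
#' likelihood-ratio test at level `alpha` and at the
#' Bonferroni-corrected level `alpha / nReplicates`. Replicates whose
#' optimizer did not converge are excluded from the significance
#' counts and tallied separately. The whole run is deterministic given
#' `baseSeed`.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree ape `phylo` tree.
#' @param K number of random classes.
#' @param nReplicates number of random assignments (default 100).
#' @param baseSeed integer; replicate r uses assignment seed
#'   `baseSeed + r - 1`.
#' @param alpha nominal test level (default 0.05).
#' @param updateBlocks parameter blocks re-optimized in each replicate
#'   fit (the SR fit always optimizes everything). The default
#'   `c("branch", "rates")` re-optimizes branch lengths and class
#'   rates while keeping nucleotide biases and positional frequencies
#'   at the SR maximum-likelihood values, which barely move between
#'   these models; use `"all"` for full re-optimization.
#' @param srFit optional precomputed SR [FitResult-class] to reuse.
#' @param control,code passed to [fitCodonModel()].
#' @return an [EnsembleResult-class].
#' @export
runRandomEnsemble <- function(aln, tree, K, nReplicates = 100L,
                              baseSeed = 1L, alpha = 0.05,
                              updateBlocks = c("branch", "rates"),
                              srFit = NULL, control = list(),
                              code = geneticCode()) {
  nReplicates <- as.integer(nReplicates)
  if (identical(updateBlocks, "all"))
    updateBlocks <- c("branch", "frequencies", "rates")
  if (is.null(srFit))
    srFit <- fitCodonModel(tree, aln, srAssignment(code), control = control,
                           code = code)
  seeds <- baseSeed + seq_len(nReplicates) - 1L
  fits <- vector("list", nReplicates)
  comparisons <- vector("list", nReplicates)
  nRaw <- 0L; nBon <- 0L; nNC <- 0L
  bics <- rep(NA_real_, nReplicates)
  n <- nSites(aln)

  for (r in seq_len(nReplicates)) {
    asn <- randomAssignment(K, seed = seeds[r], code = code)
    fit <- fitCodonModel(tree, aln, asn, start = srFit,
                         updateBlocks = updateBlocks, control = control,
                         code = code)
    fits[[r]] <- fit
    if (!fit@converged) {
      nNC <- nNC + 1L
      warning("replicate ", r, " (seed ", seeds[r],
              ") did not converge; excluded from counts", call. = FALSE)
      next
    }
    cmp <- lrTest(srFit, fit, alpha = alpha, bonferroniN = nReplicates)
    comparisons[[r]] <- cmp
    nRaw <- nRaw + cmp@significantRaw
    nBon <- nBon + cmp@significantBonferroni
    bics[r] <- bic(fit, n)
  }

  new("EnsembleResult", K = as.integer(K), nReplicates = nReplicates,
      seeds = as.numeric(seeds), srFit = srFit, fits = fits,
      comparisons = comparisons, nSignificantRaw = nRaw,
      nSignificantBonferroni = nBon, nNonConverged = nNC,
      meanBic = mean(bics, na.rm = TRUE), alpha = alpha,
      nSites = as.integer(n))
}

#' @describeIn runRandomEnsemble class count of the random models.
#' @param x an [EnsembleResult-class].
#' @export
setMethod("nClasses", "EnsembleResult", function(x) x@K)

setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult: ", object@nReplicates, " random K=", object@K,
      " models vs SR\n", sep = "")
  cat("  significant: ", object@nSignificantRaw, " (",
      object@nSignificantBonferroni, " after Bonferroni) at alpha = ",
      object@alpha, "\n", sep = "")
  cat("  mean BIC ", format(object@meanBic, digits = 8), " vs SR BIC ",
      format(bic(object@srFit, object@nSites), digits = 8),
      if (object@nNonConverged) paste0("; ", object@nNonConverged,
                                       " non-converged excluded"),
      "\n", sep = "")
})

#' Benchmark summary tables
#'
#' Renders ensemble and fit results as the two standard tables of the
#' benchmarking protocol: per alignment, (i) the number of random
#' permutations significantly better than SR per class count K, raw
#' with the Bonferroni-corrected count in parentheses ("43 (15)"), and
#' (ii) a BIC comparison across fitted models with the smallest value
#' per alignment flagged.
#'
#' @param entries named list, one element per alignment. Each element
#'   is a list with components `nTaxa`, `nSites`, `ensembles` (list of
#'   [EnsembleResult-class]) and optionally `fits` (named list of
#'   [FitResult-class] for the BIC table; ensembles contribute their
#'   mean BIC as `random K=k` and their SR fit as `SR`).
#' @return list of two data.frames: `significance` (one row per
#'   alignment, one column per K) and `bicTable` (one row per
#'   alignment, one column per model, plus `best`, the name of the
#'   smallest-BIC model).
#' @export
summarizeBenchmark <- function(entries) {
  sigCols <- list(); bicCols <- list()
  sigRows <- list(); bicRows <- list()
  for (nm in names(entries)) {
    en <- entries[[nm]]
    sig <- list(alignment = nm, N = en$nTaxa, S = en$nSites)
    bics <- list(alignment = nm)
    for (ens in en$ensembles) {
      sig[[paste0("K", ens@K)]] <-
        sprintf("%d (%d)", ens@nSignificantRaw, ens@nSignificantBonferroni)
      bics[["SR"]] <- bic(ens@srFit, ens@nSites)
      bics[[sprintf("random K=%d", ens@K)]] <- ens@meanBic
    }
    for (fn in names(en$fits))
      bics[[fn]] <- bic(en$fits[[fn]], en$nSites)
    sigRows[[nm]] <- sig; bicRows[[nm]] <- bics
  }
  toDf <- function(rows) {
    cols <- unique(unlist(lapply(rows, names)))
    out <- lapply(rows, function(r) {
      r[setdiff(cols, names(r))] <- NA
      as.data.frame(r[cols], stringsAsFactors = FALSE, check.names = FALSE)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  }
  sigDf <- if (length(sigRows)) toDf(sigRows) else
    data.frame(alignment = character(), N = integer(), S = integer())
  bicDf <- if (length(bicRows)) toDf(bicRows) else
    data.frame(alignment = character())
  if (nrow(bicDf) && ncol(bicDf) > 1L) {
    vals <- as.matrix(bicDf[, -1L, drop = FALSE])
    bicDf$best <- colnames(vals)[apply(vals, 1L, which.min)]
  }
  list(significance = sigDf, bicTable = bicDf)
}
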