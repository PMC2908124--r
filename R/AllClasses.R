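#' @import methods
NULL

#' Genetic code table
#'
#' Maps each of the 64 codons to a one-letter amino-acid code or `"*"`
#' (stop). Built by [geneticCode()] from a standard NCBI translation
#' table; the universal (standard) code is the default throughout the
#' package.
#'
#' @slot tableId character, the translation-table identifier.
#' @slot codonToResidue named character of length 64; names are codons
#'   in `A < C < G < T` lexicographic order, values are one-letter
#'   residue codes or `"*"`.
#' @export
setClass("GeneticCode",
  representation(tableId = "character", codonToResidue = "character"))

setValidity("GeneticCode", function(object) {
  ctr <- object@codonToResidue
  msgs <- character()
  if (length(ctr) != 64L) msgs <- c(msgs, "codonToResidue must map exactly 64 codons")
  if (is.null(names(ctr)) || anyDuplicated(names(ctr)))
    msgs <- c(msgs, "codon names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Ordered state space of sense codons
#'
#' The sense codons of a genetic code in deterministic lexicographic
#' order (`A < C < G < T`); all rate matrices, stationary vectors and
#' alignment state indices in the package follow this ordering. Under
#' the universal code there are 61 states.
#'
#' @slot codons character vector of sense codons, lexicographic order.
#' @slot geneticCode the [GeneticCode-class] the space was derived from.
#' @export
setClass("CodonStateSpace",
  representation(codons = "character", geneticCode = "GeneticCode"))

setValidity("CodonStateSpace", function(object) {
  res <- object@geneticCode@codonToResidue[object@codons]
  msgs <- character()
  if (any(res == "*")) msgs <- c(msgs, "state space must not contain stop codons")
  if (is.unsorted(object@codons)) msgs <- c(msgs, "codons must be in lexicographic order")
  if (length(msgs)) msgs else TRUE
})

#' Assignment of one-step residue pairs to exchangeability classes
#'
#' Partitions the one-step exchangeable amino-acid pairs (75 under the
#' universal code) into `nClasses` rate classes. The assignment acts on
#' residue *pairs*, not on residues, so no transitivity is imposed:
#' \{A,B\} and \{B,C\} may sit in one class while \{A,C\} (if it is
#' one-step exchangeable at all) sits in another.
#'
#' Class labels are integers `1..nClasses` internally; JSON
#' serialization ([writeAssignment()]) uses 0-based labels.
#'
#' @slot nClasses integer, the number of classes K (>= 1).
#' @slot classOf named integer vector; names are residue-pair keys of
#'   the form `"A:C"` (one-letter codes, alphabetically sorted within
#'   the pair), values in `1..nClasses`.
#' @export
setClass("RateClassAssignment",
  representation(nClasses = "integer", classOf = "integer"))

setValidity("RateClassAssignment", function(object) {
  msgs <- character()
  if (length(object@nClasses) != 1L || object@nClasses < 1L)
    msgs <- c(msgs, "nClasses must be a single integer >= 1")
  cl <- object@classOf
  if (is.null(names(cl))) msgs <- c(msgs, "classOf must be named by residue pair")
  if (length(cl) && (any(cl < 1L) || any(cl > object@nClasses)))
    msgs <- c(msgs, "class labels must lie in 1..nClasses")
  if (anyDuplicated(names(cl))) msgs <- c(msgs, "each pair must be assigned exactly once")
  if (length(msgs)) msgs else TRUE
})

#' Codon instantaneous rate matrix
#'
#' A time-reversible rate matrix over the sense codons, with its exact
#' stationary distribution (product of position-specific nucleotide
#' frequencies restricted to sense codons) and the expected
#' substitution rate at stationarity before normalization.
#'
#' @slot Q numeric matrix (61 x 61 under the universal code), rows and
#'   columns named by codon; off-diagonals >= 0, rows sum to zero,
#'   entries are zero between codons differing at more than one
#'   nucleotide position.
#' @slot stationary numeric stationary probability vector.
#' @slot scale numeric, expected substitutions per unit time at
#'   stationarity for the *unnormalized* matrix.
#' @slot normalized logical; if `TRUE`, `Q` has been divided by `scale`
#'   so one unit of branch length equals one expected substitution per
#'   codon site.
#' @slot stateSpace the [CodonStateSpace-class] the matrix is defined on.
#' @export
setClass("CodonRateMatrix",
  representation(Q = "matrix", stationary = "numeric", scale = "numeric",
                 normalized = "logical", stateSpace = "CodonStateSpace"))

setValidity("CodonRateMatrix", function(object) {
  msgs <- character()
  n <- length(object@stateSpace@codons)
  if (!all(dim(object@Q) == c(n, n))) msgs <- c(msgs, "Q dimension must match state space")
  if (length(object@stationary) != n) msgs <- c(msgs, "stationary length must match state space")
  if (abs(sum(object@stationary) - 1) > 1e-8) msgs <- c(msgs, "stationary must sum to 1")
  offd <- object@Q; diag(offd) <- 0
  if (any(offd < -1e-12)) msgs <- c(msgs, "off-diagonal rates must be non-negative")
  if (max(abs(rowSums(object@Q))) > 1e-8) msgs <- c(msgs, "rows of Q must sum to zero")
  if (length(msgs)) msgs else TRUE
})

#' In-frame codon alignment
#'
#' Stores one integer codon-state index per taxon and site (`NA` for
#' missing/ambiguous codons), in the ordering of the associated
#' [CodonStateSpace-class]. Construct from sequences with
#' [codonAlignment()] or [readCodonFasta()], or simulate with
#' [simulateAlignment()].
#'
#' @slot states integer matrix, taxa in rows (rownames = taxon labels),
#'   codon sites in columns; values in `1..n_states` or `NA`.
#' @slot stateSpace the [CodonStateSpace-class] indexing the states.
#' @slot metadata list of optional annotations (simulation ground
#'   truth, event logs, source file).
#' @export
setClass("CodonAlignment",
  representation(states = "matrix", stateSpace = "CodonStateSpace",
                 metadata = "list"))

setValidity("CodonAlignment", function(object) {
  msgs <- character()
  s <- object@states
  if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
    msgs <- c(msgs, "taxa must have unique names")
  n <- length(object@stateSpace@codons)
  v <- s[!is.na(s)]
  if (length(v) && (any(v < 1L) || any(v > n)))
    msgs <- c(msgs, "state indices out of range for the state space")
  if (length(msgs)) msgs else TRUE
})

#' Result of a maximum-likelihood model fit
#'
#' @slot logLik numeric, maximized log-likelihood.
#' @slot estimates list with components `branchLengths`, `theta`
#'   (nucleotide biases), `pi` (3 x 4 positional frequencies), `rho`
#'   (per-class exchangeabilities).
#' @slot nFreeParameters integer, total free parameters (branch lengths
#'   + free biases + free frequencies + effective rate classes).
#' @slot rateParameterCount integer, the effective (non-empty)
#'   rate-class count alone.
#' @slot converged logical.
#' @slot boundary logical, `TRUE` when any rate estimate sits on its
#'   optimization bound.
#' @slot modelDescriptor list describing the model (assignment, bias
#'   submodel, frequency policy, branch-length policy).
#' @slot tree the `phylo` tree with optimized branch lengths.
#' @slot seed numeric, optimizer restart seed (`NA` if none).
#' @export
setClass("FitResult",
  representation(logLik = "numeric", estimates = "list",
                 nFreeParameters = "integer", rateParameterCount = "integer",
                 converged = "logical", boundary = "logical",
                 modelDescriptor = "list", tree = "ANY", seed = "numeric"))

setValidity("FitResult", function(object) {
  if (isTRUE(object@converged) && !is.finite(object@logLik))
    "a converged fit must have a finite log-likelihood" else TRUE
})

#' Likelihood-ratio comparison of two nested fits
#'
#' @slot lrStatistic numeric, `2 * (LL_alt - LL_null)` (clamped to 0
#'   when negative within tolerance).
#' @slot df integer degrees of freedom (difference in free parameters).
#' @slot pValue numeric upper-tail chi-square probability.
#' @slot alpha numeric nominal level.
#' @slot bonferroniAlpha numeric corrected level used for
#'   `significantBonferroni`.
#' @slot significantRaw,significantBonferroni logical flags.
#' @export
setClass("ModelComparison",
  representation(lrStatistic = "numeric", df = "integer", pValue = "numeric",
                 alpha = "numeric", bonferroniAlpha = "numeric",
                 significantRaw = "logical", significantBonferroni = "logical"))

setValidity("ModelComparison", function(object) {
  msgs <- character()
  if (object@df < 1L) msgs <- c(msgs, "df must be >= 1")
  if (object@pValue < 0 || object@pValue > 1) msgs <- c(msgs, "p-value must be in [0, 1]")
  if (object@lrStatistic < 0) msgs <- c(msgs, "LR statistic must be non-negative after clamping")
  if (object@significantBonferroni && !object@significantRaw)
    msgs <- c(msgs, "Bonferroni significance implies raw significance")
  if (length(msgs)) msgs else TRUE
})

#' Random-model ensemble benchmark result
#'
#' Per-replicate fits and likelihood-ratio comparisons for the
#' random-assignment benchmarking protocol: an SR fit plus
#' `nReplicates` fits of models whose 75 one-step residue pairs are
#' randomly partitioned into `K` classes.
#'
#' @slot K integer class count of the random models.
#' @slot nReplicates integer number of random assignments fitted.
#' @slot seeds numeric per-replicate assignment seeds.
#' @slot srFit the null [FitResult-class].
#' @slot fits list of per-replicate [FitResult-class] objects.
#' @slot comparisons list of per-replicate [ModelComparison-class]
#'   objects (`NULL` where the replicate did not converge).
#' @slot nSignificantRaw,nSignificantBonferroni integer counts over
#'   converged replicates.
#' @slot nNonConverged integer count of replicates excluded from the
#'   significance tally.
#' @slot meanBic numeric mean BIC over converged replicates.
#' @slot alpha numeric nominal test level.
#' @slot nSites integer codon sites used as the BIC sample size.
#' @export
setClass("EnsembleResult",
  representation(K = "integer", nReplicates = "integer", seeds = "numeric",
                 srFit = "FitResult", fits = "list", comparisons = "list",
                 nSignificantRaw = "integer", nSignificantBonferroni = "integer",
                 nNonConverged = "integer", meanBic = "numeric",
                 alpha = "numeric", nSites = "integer"))

setValidity("EnsembleResult", function(object) {
  msgs <- character()
  if (object@nSignificantRaw > object@nReplicates ||
      object@nSignificantBonferroni > object@nReplicates)
    msgs <- c(msgs, "significance counts cannot exceed replicate count")
  if (object@nSignificantBonferroni > object@nSignificantRaw)
    msgs <- c(msgs, "Bonferroni count cannot exceed raw count")
  if (length(msgs)) msgs else TRUE
})
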