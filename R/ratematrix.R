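NUC_PAIRS <- c("A:C", "A:G", "A:T", "C:G", "C:T", "G:T")

#' Default parameter values
#'
#' Neutral defaults for the rate-matrix parameters: unit nucleotide
#' biases (named by unordered nucleotide pair; the `A:G` entry is the
#' identifiability reference and is fixed at 1 during fitting) and
#' uniform position-specific nucleotide frequencies (3 x 4, rows =
#' codon positions, columns = A, C, G, T; each row sums to 1).
#'
#' @return `defaultTheta()` a named numeric of length 6;
#'   `defaultPi()` a 3 x 4 numeric matrix.
#' @export
defaultTheta <- function() {
  th <- rep(1, 6)
  names(th) <- NUC_PAIRS
  th
}

#' @rdname defaultTheta
#' @export
defaultPi <- function() {
  p <- matrix(0.25, 3, 4, dimnames = list(paste0("pos", 1:3), NUCLEOTIDES))
  p
}

checkTheta <- function(theta) {
  if (is.null(names(theta))) names(theta) <- NUC_PAIRS
  if (!setequal(names(theta), NUC_PAIRS))
    stop("theta must be named by the 6 unordered nucleotide pairs ",
         paste(NUC_PAIRS, collapse = ", "), call. = FALSE)
  theta <- theta[NUC_PAIRS]
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("nucleotide biases must be finite and non-negative", call. = FALSE)
  theta
}

checkPi <- function(pi) {
  pi <- as.matrix(pi)
  if (!all(dim(pi) == c(3L, 4L)))
    stop("pi must be a 3 x 4 matrix (codon position x nucleotide)", call. = FALSE)
  colnames(pi) <- NUCLEOTIDES
  if (any(!is.finite(pi)) || any(pi <= 0))
    stop("positional frequencies must be positive", call. = FALSE)
  if (max(abs(rowSums(pi) - 1)) > 1e-6)
    stop("each row of pi must sum to 1", call. = FALSE)
  pi / rowSums(pi)
}

#' Stationary distribution induced by positional frequencies
#'
#' The stationary law of every rate matrix in the family is the product
#' of the position-specific nucleotide frequencies, restricted to the
#' sense codons and renormalized:
#' `stationary(c1 c2 c3) = pi[1, c1] * pi[2, c2] * pi[3, c3] / Z`.
#'
#' @param pi 3 x 4 positional frequency matrix (see [defaultPi()]).
#' @param code a [GeneticCode-class].
#' @return named numeric probability vector over the sense codons.
#' @export
stationaryDistribution <- function(pi, code = geneticCode()) {
  pi <- checkPi(pi)
  space <- senseCodonSpace(code)
  mat <- do.call(rbind, strsplit(space@codons, ""))
  w <- pi[1L, mat[, 1L]] * pi[2L, mat[, 2L]] * pi[3L, mat[, 3L]]
  names(w) <- space@codons
  w / sum(w)
}

#' Build a codon rate matrix
#'
#' Assembles the instantaneous rate matrix of the time-reversible codon
#' model family. For a one-step event `i -> j` replacing nucleotide `x`
#' by `y` at codon position `k`:
#'
#' \deqn{q_{ij} = \rho_{c(aa_i, aa_j)}\,\theta_{xy}\,\pi_{k,y}}
#'
#' for non-synonymous events, where `c(.,.)` is the rate class of the
#' residue pair under `assignment`; synonymous events use the fixed
#' baseline exchangeability 1 in place of `rho`, so every `rho` is a
#' non-synonymous/synonymous rate ratio (for the SR model, the
#' classical omega). Multi-step codon pairs have rate 0; the diagonal
#' makes rows sum to zero.
#'
#' @param assignment a [RateClassAssignment-class].
#' @param rho numeric exchangeabilities, one per class (recycled if a
#'   scalar); all `>= 0`.
#' @param theta named numeric of length 6, nucleotide biases per
#'   unordered pair (see [defaultTheta()]).
#' @param pi 3 x 4 positional nucleotide frequencies.
#' @param code a [GeneticCode-class].
#' @param normalize if `TRUE` (default), divide `Q` by its stationary
#'   expected rate so one unit of branch length equals one expected
#'   substitution per codon site.
#' @return a [CodonRateMatrix-class].
#' @examples
#' m <- codonRateMatrix(srAssignment(), rho = 0.3)
#' max(abs(rowSums(m@Q)))  # ~0
#' @export
codonRateMatrix <- function(assignment, rho, theta = defaultTheta(),
                            pi = defaultPi(), code = geneticCode(),
                            normalize = TRUE) {
  stopifnot(is(assignment, "RateClassAssignment"))
  K <- assignment@nClasses
  if (length(rho) == 1L) rho <- rep(rho, K)
  if (length(rho) != K)
    stop("rho must have one value per class (", K, ")", call. = FALSE)
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("exchangeabilities must be finite and non-negative", call. = FALSE)
  theta <- checkTheta(theta)
  pi <- checkPi(pi)

  space <- senseCodonSpace(code)
  n <- length(space@codons)
  ev <- oneStepEvents(code)

  pairKey <- residuePairKey(ev$fromResidue, ev$toResidue)
  exch <- ifelse(ev$synonymous, 1, rho[assignment@classOf[pairKey]])
  nucKey <- residuePairKey(ev$fromNuc, ev$toNuc)
  rate <- exch * theta[nucKey] * pi[cbind(ev$position, match(ev$toNuc, NUCLEOTIDES))]

  Q <- matrix(0, n, n, dimnames = list(space@codons, space@codons))
  Q[cbind(ev$fromState, ev$toState)] <- rate
  diag(Q) <- -rowSums(Q)

  statn <- stationaryDistribution(pi, code)
  scale <- sum(statn * -diag(Q))
  if (normalize && scale > 0) Q <- Q / scale

  new("CodonRateMatrix", Q = Q, stationary = statn, scale = scale,
      normalized = isTRUE(normalize), stateSpace = space)
}

#' @describeIn codonRateMatrix codons indexing the matrix.
#' @param x a [CodonRateMatrix-class].
#' @export
setMethod("codons", "CodonRateMatrix", function(x) x@stateSpace@codons)

#' @describeIn codonRateMatrix stationary distribution of the matrix.
#' @export
setMethod("stationary", "CodonRateMatrix", function(x) x@stationary)

setMethod("show", "CodonRateMatrix", function(object) {
  cat("CodonRateMatrix: ", nrow(object@Q), " x ", ncol(object@Q),
      if (object@normalized) ", normalized (1 expected substitution/site/unit time)"
      else paste0(", unnormalized (stationary rate ", signif(object@scale, 4), ")"),
      "\n", sep = "")
})

# Spectral decomposition of a reversible Q: with D = diag(stationary),
# S = D^{1/2} Q D^{-1/2} is symmetric; P(t) = A exp(L t) B with
# A = D^{-1/2} V, B = t(V) D^{1/2}. One decomposition serves every
# branch length.
eigenSystem <- function(model) {
  p <- model@stationary
  sq <- sqrt(p)
  S <- model@Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2  # symmetrize away rounding noise
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       A = e$vectors / sq,
       B = t(e$vectors * sq),
       stationary = p)
}

probFromEigen <- function(es, t) {
  es$A %*% (exp(es$values * t) * es$B)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)`, computed by spectral decomposition of the
#' reversible generator (exact for this model family and stable for
#' any branch length).
#'
#' @param model a [CodonRateMatrix-class].
#' @param t branch length, `>= 0` (expected substitutions per codon
#'   site when the matrix is normalized).
#' @return a stochastic matrix of the same dimension as `Q`.
#' @examples
#' m <- codonRateMatrix(srAssignment(), rho = 0.5)
#' range(rowSums(transitionMatrix(m, 0.2)))  # 1 1
#' @export
transitionMatrix <- function(model, t) {
  stopifnot(is(model, "CodonRateMatrix"))
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length t must be a single non-negative number", call. = FALSE)
  P <- probFromEigen(eigenSystem(model), t)
  P[P < 0] <- 0  # clip eigen-roundoff noise
  dimnames(P) <- dimnames(model@Q)
  P
}
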