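# Maximum-likelihood fitting by block coordinate ascent:
# (1) branch lengths by exact 1-D coordinate descent (.sweepBranches),
# (2) nucleotide biases + positional frequencies by bounded
#     quasi-Newton (L-BFGS-B) on transformed coordinates,
# (3) class exchangeabilities likewise.
# Blocks repeat until the log-likelihood gain falls below a relative
# tolerance. Every block starts from the current point and only
# accepts improvements, so the log-likelihood is non-decreasing across
# iterations and the final fit is never worse than its initialization
# (warm starts from a nested model therefore guarantee the nesting
# inequality LL_alt >= LL_null).

# Fast Q builder with all event bookkeeping precomputed once per
# (assignment, code).
.makeQBuilder <- function(assignment, code) {
  space <- senseCodonSpace(code)
  n <- length(space@codons)
  ev <- oneStepEvents(code)
  syn <- ev$synonymous
  pairClass <- unname(assignment@classOf[residuePairKey(ev$fromResidue, ev$toResidue)])
  nucIdx <- match(residuePairKey(ev$fromNuc, ev$toNuc), NUC_PAIRS)
  piIdx <- cbind(ev$position, match(ev$toNuc, NUCLEOTIDES))
  qIdx <- cbind(ev$fromState, ev$toState)
  codNuc <- do.call(rbind, strsplit(space@codons, ""))
  codNucIdx <- matrix(match(codNuc, NUCLEOTIDES), n, 3)
  Q0 <- matrix(0, n, n, dimnames = list(space@codons, space@codons))
  nsIdx <- which(!syn)

  function(rho, theta, pi) {
    exch <- rep(1, nrow(ev))
    exch[nsIdx] <- rho[pairClass[nsIdx]]
    rate <- exch * theta[nucIdx] * pi[piIdx]
    Q <- Q0
    Q[qIdx] <- rate
    diag(Q) <- -rowSums(Q)
    w <- pi[1L, codNucIdx[, 1L]] * pi[2L, codNucIdx[, 2L]] * pi[3L, codNucIdx[, 3L]]
    statn <- w / sum(w)
    scale <- sum(statn * -diag(Q))
    list(Q = Q / scale, stationary = statn, scale = scale)
  }
}

.eigenFromQ <- function(Q, stationary) {
  sq <- sqrt(stationary)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, A = e$vectors / sq, B = t(e$vectors * sq),
       stationary = stationary)
}

# positional frequencies <-> multinomial logits (reference: A)
.piToLogits <- function(pi) as.vector(log(pi[, -1L] / pi[, 1L]))
.logitsToPi <- function(z) {
  zm <- cbind(0, matrix(z, 3, 3))
  zm <- zm - apply(zm, 1L, max)
  p <- exp(zm)
  p <- p / rowSums(p)
  dimnames(p) <- list(paste0("pos", 1:3), NUCLEOTIDES)
  p
}

# free nucleotide-bias coordinates for a bias submodel
.thetaFreeNames <- function(biasModel) {
  switch(biasModel,
         rev = setdiff(NUC_PAIRS, "A:G"),
         hky = "tv",
         stop("unknown bias submodel '", biasModel, "'", call. = FALSE))
}

.buildTheta <- function(free, biasModel) {
  th <- defaultTheta()
  if (biasModel == "rev") {
    th[names(free)] <- free
  } else {                      # hky: transitions fixed at 1, one
    tv <- unname(free[1L])      # shared transversion rate
    th[c("A:C", "A:T", "C:G", "G:T")] <- tv
  }
  th
}

.thetaToFree <- function(theta, biasModel) {
  if (biasModel == "rev") theta[setdiff(NUC_PAIRS, "A:G")]
  else c(tv = unname(mean(theta[c("A:C", "A:T", "C:G", "G:T")])))
}

# Branch-length initialization from pairwise codon p-distances
# (JC-style corrected, projected on the topology by least squares).
.initBranchLengths <- function(tree, aln, fallback = 0.1,
                               bounds = c(1e-6, 30)) {
  bl <- tryCatch({
    st <- aln@states
    nt <- nrow(st)
    labs <- rownames(st)
    d <- matrix(0.5, nt, nt, dimnames = list(labs, labs))
    for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
      ok <- !is.na(st[i, ]) & !is.na(st[j, ])
      p <- if (any(ok)) mean(st[i, ok] != st[j, ok]) else 0.5
      # Poisson-correct assuming ~60/61 of random codon pairs differ
      d[i, j] <- d[j, i] <- if (p < 0.95) -log(1 - p * 61 / 60) * 60 / 61 else 3
    }
    ft <- phangorn::nnls.tree(d, ape::unroot(tree), method = "unrooted")
    ft <- ape::reorder.phylo(ft, "postorder")
    pmin(pmax(ft$edge.length, bounds[1L]), bounds[2L])
  }, error = function(e) NULL)
  if (is.null(bl)) bl <- rep(fallback, nrow(ape::reorder.phylo(tree, "postorder")$edge))
  bl
}

#' Free-parameter accounting for a model configuration
#'
#' Counts the free parameters of a fit: one per branch, the free
#' nucleotide biases (5 for the REV-like bias submodel with the A:G
#' rate fixed at 1; 1 for HKY-like), the free positional frequencies
#' (9 when ML-optimized, 0 when fixed to observed proportions), and
#' one exchangeability per *effective* (non-empty) rate class. The
#' rate-class count alone is also reported, as used in BIC tables.
#'
#' @param assignment a [RateClassAssignment-class].
#' @param tree an ape `phylo` object (its edge count is the
#'   branch-length parameter count).
#' @param freqPolicy `"ml"` or `"observed"`.
#' @param biasModel `"rev"` or `"hky"`.
#' @return list with `total`, `rateParameters`, `branches`, `biases`,
#'   `frequencies`.
#' @examples
#' tr <- randomTree(13, seed = 1)
#' countFreeParameters(srAssignment(), tr)$total  # 23 + 5 + 9 + 1 = 38
#' @export
countFreeParameters <- function(assignment, tree,
                                freqPolicy = c("ml", "observed"),
                                biasModel = c("rev", "hky")) {
  freqPolicy <- match.arg(freqPolicy)
  biasModel <- match.arg(biasModel)
  branches <- nrow(tree$edge)
  biases <- if (biasModel == "rev") 5L else 1L
  freqs <- if (freqPolicy == "ml") 9L else 0L
  rates <- effectiveClasses(assignment)
  list(total = branches + biases + freqs + rates,
       rateParameters = rates, branches = branches,
       biases = biases, frequencies = freqs)
}

#' Fit a codon model by maximum likelihood
#'
#' Jointly estimates branch lengths, nucleotide biases, positional
#' frequencies and per-class exchangeabilities on a fixed topology, by
#' block coordinate ascent (branch lengths by exact one-dimensional
#' coordinate descent; the other blocks by bounded quasi-Newton). The
#' log-likelihood is non-decreasing over iterations and the result is
#' never below the likelihood of the initialization point.
#'
#' @param tree ape `phylo` tree (fixed topology; branch lengths used
#'   as initial values when present and `start` is not given).
#' @param aln a [CodonAlignment-class].
#' @param assignment a [RateClassAssignment-class] defining the model.
#' @param freqPolicy `"ml"` to maximum-likelihood-optimize the 9 free
#'   positional frequencies (the default, as in the benchmarking
#'   protocol) or `"observed"` to fix them at observed proportions.
#' @param biasModel `"rev"` (5 free nucleotide biases, A:G fixed at 1)
#'   or `"hky"` (transitions fixed at 1, one shared transversion bias).
#' @param start optional [FitResult-class] on the same tree/alignment
#'   used as a warm start; parameters of a nested assignment are
#'   expanded to the new classes, guaranteeing
#'   `logLik(fit) >= logLik(start)`.
#' @param updateBlocks character subset of
#'   `c("branch", "frequencies", "rates")`: the parameter blocks the
#'   optimizer updates. Blocks left out keep their initial values
#'   (e.g. drop `"branch"` to freeze branch lengths).
#' @param restarts number of additional random restarts with jittered
#'   rates/biases (seeded); the best fit is returned.
#' @param seed seed for the restart jitter (required if `restarts > 0`).
#' @param control list overriding optimizer settings: `relTol`
#'   (relative log-likelihood tolerance, default `1e-8`), `maxOuter`
#'   (outer block sweeps, default 40), `innerMaxit` (quasi-Newton
#'   iterations per block, default 25), `freezeTol` (a block gaining
#'   less than this many log-units in one sweep is skipped afterwards,
#'   default `1e-3`), `rateBounds` (default
#'   `c(1e-6, 100)` for rho and theta), `blBounds` (default
#'   `c(1e-9, 30)`).
#' @param code a [GeneticCode-class].
#' @return a [FitResult-class].
#' @export
fitCodonModel <- function(tree, aln, assignment,
                          freqPolicy = c("ml", "observed"),
                          biasModel = c("rev", "hky"),
                          start = NULL,
                          updateBlocks = c("branch", "frequencies", "rates"),
                          restarts = 0L, seed = NA_integer_,
                          control = list(), code = geneticCode()) {
  freqPolicy <- match.arg(freqPolicy)
  biasModel <- match.arg(biasModel)
  stopifnot(is(aln, "CodonAlignment"), is(assignment, "RateClassAssignment"))
  ctl <- utils::modifyList(list(relTol = 1e-8, maxOuter = 40L,
                                innerMaxit = 25L, freezeTol = 1e-3,
                                rateBounds = c(1e-6, 100),
                                blBounds = c(1e-9, 30)), control)
  updateBlocks <- match.arg(updateBlocks,
                            c("branch", "frequencies", "rates"),
                            several.ok = TRUE)

  pp <- .preparePruning(tree, aln)
  qb <- .makeQBuilder(assignment, code)
  K <- assignment@nClasses
  occ <- sort(unique(assignment@classOf))

  # ---- initial values ----
  if (!is.null(start)) {
    stopifnot(is(start, "FitResult"))
    stree <- ape::reorder.phylo(start@tree, "postorder")
    if (!identical(stree$edge, pp$tree$edge))
      stop("warm start requires the same tree topology", call. = FALSE)
    blen <- stree$edge.length
    theta <- start@estimates$theta
    piM <- start@estimates$pi
    sAsn <- start@modelDescriptor$assignment
    rho <- rep(1, K)
    if (!is.null(sAsn) && isNestedAssignment(sAsn, assignment)) {
      oldOf <- vapply(split(sAsn@classOf, assignment@classOf),
                      function(v) v[1L], integer(1))
      rho[as.integer(names(oldOf))] <- start@estimates$rho[oldOf]
    }
  } else {
    blen <- if ("branch" %in% updateBlocks)
      .initBranchLengths(tree, aln, bounds = ctl$blBounds)
    else pp$tree$edge.length
    theta <- defaultTheta()
    piM <- observedPositionalFreqs(aln)
    rho <- rep(1, K)
  }
  if (freqPolicy == "observed") piM <- observedPositionalFreqs(aln)

  runOnce <- function(blen, theta, piM, rho) {
    .fitLoop(pp, qb, blen, theta, piM, rho, occ, freqPolicy, biasModel,
             updateBlocks, ctl)
  }
  best <- runOnce(blen, theta, piM, rho)
  if (restarts > 0L) {
    if (is.na(seed)) stop("restarts require a seed", call. = FALSE)
    jit <- withPreservedSeed(seed, replicate(restarts, list(
      rho = pmin(pmax(rho * exp(stats::rnorm(K, 0, 0.5)), ctl$rateBounds[1L]),
                 ctl$rateBounds[2L]),
      theta = {
        t2 <- theta * exp(stats::rnorm(6, 0, 0.3)); t2["A:G"] <- 1; t2
      }), simplify = FALSE))
    for (j in jit) {
      cand <- runOnce(blen, j$theta, piM, j$rho)
      if (cand$logLik > best$logLik) best <- cand
    }
  }

  fitTree <- pp$tree
  fitTree$edge.length <- best$blen
  cnt <- countFreeParameters(assignment, fitTree, freqPolicy, biasModel)
  onBound <- function(x, b) any(x <= b[1L] * (1 + 1e-6)) || any(x >= b[2L] * (1 - 1e-6))
  boundary <- onBound(best$rho[occ], ctl$rateBounds) ||
    ("frequencies" %in% updateBlocks &&
       onBound(.buildTheta(best$thetaFree, biasModel)[.thetaFreeNames(biasModel)[1L]],
               ctl$rateBounds)) ||
    ("branch" %in% updateBlocks && onBound(best$blen, ctl$blBounds))

  new("FitResult",
      logLik = best$logLik,
      estimates = list(branchLengths = best$blen, theta = best$theta,
                       pi = best$piM, rho = best$rho),
      nFreeParameters = as.integer(cnt$total),
      rateParameterCount = as.integer(cnt$rateParameters),
      converged = best$converged, boundary = boundary,
      modelDescriptor = list(assignment = assignment, biasModel = biasModel,
                             freqPolicy = freqPolicy,
                             updateBlocks = updateBlocks),
      tree = fitTree, seed = as.numeric(seed))
}

# inner block-coordinate loop
.fitLoop <- function(pp, qb, blen, theta, piM, rho, occ, freqPolicy,
                     biasModel, updateBlocks, ctl) {
  lb <- log(ctl$rateBounds[1L]); ub <- log(ctl$rateBounds[2L])
  evalLL <- function(blen, theta, piM, rho) {
    m <- qb(rho, theta, piM)
    .pruneLogLik(pp, .eigenFromQ(m$Q, m$stationary), blen)
  }
  # negated objective plus a memoized forward-difference gradient
  # (one extra evaluation per coordinate instead of optim's two)
  mkObjective <- function(f) {
    lastP <- NULL; lastV <- NA_real_
    fn <- function(p) {
      v <- tryCatch(f(p), error = function(e) NA_real_)
      v <- if (!is.finite(v)) 1e10 else -v
      lastP <<- p; lastV <<- v
      v
    }
    gr <- function(p) {
      v0 <- if (identical(p, lastP)) lastV else fn(p)
      eps <- 1e-6  # parameters live on log/logit scales
      g <- numeric(length(p))
      for (i in seq_along(p)) {
        p2 <- p; p2[i] <- p2[i] + eps
        v <- tryCatch(f(p2), error = function(e) NA_real_)
        v <- if (!is.finite(v)) 1e10 else -v
        g[i] <- (v - v0) / eps
      }
      g
    }
    list(fn = fn, gr = gr)
  }

  thetaFree <- .thetaToFree(theta, biasModel)
  ll <- evalLL(blen, theta, piM, rho)
  converged <- FALSE
  # a block whose last sweep gained less than freezeTol log-units is
  # skipped afterwards; the expensive frequency block typically
  # converges in the first couple of sweeps
  active <- c(branch = "branch" %in% updateBlocks,
              frequencies = "frequencies" %in% updateBlocks,
              rates = "rates" %in% updateBlocks)

  for (outer in seq_len(ctl$maxOuter)) {
    llPrev <- ll

    if (active[["branch"]]) {
      m <- qb(rho, theta, piM)
      es <- .eigenFromQ(m$Q, m$stationary)
      blNew <- .sweepBranches(pp, es, blen, lower = ctl$blBounds[1L],
                              upper = ctl$blBounds[2L])
      llNew <- .pruneLogLik(pp, es, blNew)
      if (llNew > ll) { blen <- blNew; ll <- llNew }
    }

    if (active[["frequencies"]]) {
      llBefore <- ll
      nTh <- length(thetaFree)
      par0 <- log(pmin(pmax(thetaFree, ctl$rateBounds[1L]), ctl$rateBounds[2L]))
      lo <- rep(lb, nTh); hi <- rep(ub, nTh)
      if (freqPolicy == "ml") {
        par0 <- c(par0, .piToLogits(piM))
        lo <- c(lo, rep(-12, 9L)); hi <- c(hi, rep(12, 9L))
      }
      obj <- function(p) {
        tf <- exp(p[seq_len(nTh)]); names(tf) <- names(thetaFree)
        pm <- if (freqPolicy == "ml") .logitsToPi(p[-seq_len(nTh)]) else piM
        evalLL(blen, .buildTheta(tf, biasModel), pm, rho)
      }
      ob <- mkObjective(obj)
      o <- stats::optim(par0, ob$fn, ob$gr, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = ctl$innerMaxit))
      if (-o$value > ll) {
        ll <- -o$value
        thetaFree <- exp(o$par[seq_len(nTh)]); names(thetaFree) <- names(.thetaToFree(defaultTheta(), biasModel))
        theta <- .buildTheta(thetaFree, biasModel)
        if (freqPolicy == "ml") piM <- .logitsToPi(o$par[-seq_len(nTh)])
      }
      if (ll - llBefore < ctl$freezeTol) active[["frequencies"]] <- FALSE
    }

    if (active[["rates"]]) {
      par0 <- log(pmin(pmax(rho[occ], ctl$rateBounds[1L]), ctl$rateBounds[2L]))
      obj <- function(p) {
        r <- rho; r[occ] <- exp(p)
        evalLL(blen, theta, piM, r)
      }
      ob <- mkObjective(obj)
      o <- stats::optim(par0, ob$fn, ob$gr, method = "L-BFGS-B",
                        lower = rep(lb, length(occ)), upper = rep(ub, length(occ)),
                        control = list(maxit = ctl$innerMaxit))
      if (-o$value > ll) { ll <- -o$value; rho[occ] <- exp(o$par) }
    }

    if (ll - llPrev < ctl$relTol * max(1, abs(ll))) { converged <- TRUE; break }
  }

  list(logLik = ll, blen = blen, theta = theta, thetaFree = thetaFree,
       piM = piM, rho = rho, converged = converged)
}

#' @describeIn fitCodonModel maximized log-likelihood of a fit.
#' @param object,x a [FitResult-class].
#' @param ... ignored.
#' @export
setMethod("logLik", "FitResult", function(object, ...) {
  structure(object@logLik, df = object@nFreeParameters, class = "logLik")
})

#' @describeIn fitCodonModel parameter estimates of a fit.
#' @export
setMethod("estimates", "FitResult", function(x) x@estimates)

#' @describeIn fitCodonModel total free-parameter count of a fit.
#' @export
setMethod("nFreeParameters", "FitResult", function(x) x@nFreeParameters)

#' @describeIn fitCodonModel convergence flag of a fit.
#' @export
setMethod("converged", "FitResult", function(x) x@converged)

setMethod("show", "FitResult", function(object) {
  a <- object@modelDescriptor$assignment
  cat("FitResult: ", if (!is.null(a)) paste0(effectiveClasses(a), "-class model, "),
      "logLik = ", format(object@logLik, digits = 10),
      ", ", object@nFreeParameters, " free parameters (",
      object@rateParameterCount, " rates)",
      if (!object@converged) " [NOT CONVERGED]",
      if (object@boundary) " [boundary]", "\n", sep = "")
  cat("  rho:", paste(signif(object@estimates$rho, 4), collapse = " "), "\n")
})
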