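# Phylogenetic likelihood engine.
#
# Likelihoods are evaluated by Felsenstein pruning over compressed site
# patterns, with per-node rescaling of partial likelihoods (log-scale
# accumulators) so arbitrarily large trees cannot underflow. Transition
# matrices come from one spectral decomposition of the reversible
# generator per Q (eigenSystem/probFromEigen in ratematrix.R); a branch
# length then only costs exp() of 61 eigenvalues.

.checkTreeAln <- function(tree, aln) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object", call. = FALSE)
  missing <- setdiff(tree$tip.label, taxa(aln))
  extra <- setdiff(taxa(aln), tree$tip.label)
  if (length(missing) || length(extra))
    stop("tree/alignment taxon mismatch; in tree only: ",
         paste(missing, collapse = ", "), "; in alignment only: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  invisible(TRUE)
}

# Compress alignment columns into unique site patterns with counts.
.compressPatterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]))
}

# Precompute everything about (tree, alignment) that does not depend on
# model parameters.
.preparePruning <- function(tree, aln) {
  .checkTreeAln(tree, aln)
  tree <- ape::reorder.phylo(tree, "postorder")
  cp <- .compressPatterns(aln@states)
  ntip <- length(tree$tip.label)
  tipStates <- cp$states[tree$tip.label, , drop = FALSE]
  edge <- tree$edge
  childEdges <- split(seq_len(nrow(edge)), edge[, 1L])
  nNodes <- ntip + tree$Nnode
  list(tree = tree, edge = edge, ntip = ntip,
       nNodes = nNodes, root = ntip + 1L,
       tipStates = tipStates, weights = cp$weights,
       npat = ncol(cp$states), childEdges = childEdges,
       # per-node rescaling of partials is only needed on trees deep
       # enough to underflow doubles; skipping it elsewhere saves
       # substantial time in the optimizer's inner loop
       rescale = nNodes > 60L)
}

# Tip message: columns of P selected by the observed states; missing
# states contribute a vector of ones.
.tipMessage <- function(P, st, n, npat) {
  ok <- !is.na(st)
  if (all(ok)) return(P[, st, drop = FALSE])
  X <- matrix(1, n, npat)
  X[, ok] <- P[, st[ok], drop = FALSE]
  X
}

# Post-order (down) pass. Returns the log-likelihood and, if keep =
# TRUE, the per-edge messages M (child partials propagated through the
# edge), their log-scalers, the normalized per-node down partials, and
# the per-edge transition matrices -- the inputs of the up pass.
.downPass <- function(pp, es, blen, keep = FALSE) {
  n <- length(es$stationary)
  npat <- pp$npat
  edge <- pp$edge
  rescale <- pp$rescale
  down <- vector("list", pp$nNodes)
  ls <- if (rescale) vector("list", pp$nNodes) else NULL
  M <- if (keep) vector("list", nrow(edge)) else NULL
  A <- es$A; B <- es$B; la <- es$values
  zero <- numeric(npat)

  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1L]; v <- edge[e, 2L]
    P <- A %*% (exp(la * blen[e]) * B)
    if (v <= pp$ntip) {
      X <- .tipMessage(P, pp$tipStates[v, ], n, npat)
      lsX <- zero
    } else {
      if (rescale) {
        # finalize (normalize) the child's accumulated partials
        s <- .colSums(down[[v]], n, npat)
        s[s <= 0] <- .Machine$double.xmin
        down[[v]] <- down[[v]] / rep(s, each = n)
        ls[[v]] <- ls[[v]] + log(s)
        lsX <- ls[[v]]
      }
      X <- P %*% down[[v]]
    }
    if (is.null(down[[u]])) {
      down[[u]] <- X
      if (rescale) ls[[u]] <- lsX
    } else {
      down[[u]] <- down[[u]] * X
      if (rescale) ls[[u]] <- ls[[u]] + lsX
    }
    if (keep) M[[e]] <- X
  }

  r <- pp$root
  L <- .colSums(es$stationary * down[[r]], n, npat)
  L[L <= 0] <- .Machine$double.xmin
  ll <- sum(pp$weights * (log(L) + if (rescale) ls[[r]] else 0))
  list(logLik = ll, down = down, M = M)
}

# Log-likelihood for a fixed model and branch lengths.
.pruneLogLik <- function(pp, es, blen) .downPass(pp, es, blen)$logLik

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over compressed site patterns on a fixed tree,
#' with the root weighted by the model's stationary distribution (root
#' placement is irrelevant by time reversibility). Gaps/ambiguous
#' codons (missing states) contribute partial-likelihood vectors of
#' ones. A single-taxon alignment needs no tree (`tree = NULL`) and
#' gives `sum(log(stationary[state]))`.
#'
#' @param tree an ape `phylo` tree with branch lengths, or `NULL` for a
#'   single-taxon alignment.
#' @param aln a [CodonAlignment-class].
#' @param model a [CodonRateMatrix-class].
#' @return the log-likelihood (numeric scalar).
#' @export
codonLogLik <- function(tree, aln, model) {
  stopifnot(is(aln, "CodonAlignment"), is(model, "CodonRateMatrix"))
  if (is.null(tree) || nTaxa(aln) == 1L) {
    if (nTaxa(aln) != 1L)
      stop("a tree is required for alignments with more than one taxon",
           call. = FALSE)
    st <- aln@states[1L, ]
    return(sum(log(model@stationary[st[!is.na(st)]])))
  }
  pp <- .preparePruning(tree, aln)
  .pruneLogLik(pp, eigenSystem(model), pp$tree$edge.length)
}

# ---- branch-length optimization -------------------------------------
#
# One sweep of exact coordinate descent over branch lengths. Processing
# edges root-to-tips (DFS), each edge sees (i) 'up' messages already
# refreshed for the updated lengths above it, and (ii) 'down' messages
# at their current (not-yet-updated) lengths below it, so every 1-D
# optimization is exact given the current value of all other branches
# and the sweep is monotone in the log-likelihood. The 1-D objective
# along an edge reduces, via the spectral form P(t) = A exp(Lt) B, to
#   sum_pat w * log( sum_k exp(lambda_k t) * ab[k, pat] )
# with ab precomputed from the flanking partials, so Brent iterations
# cost O(61 * npat).

.edgeObjective <- function(la, ab, w) {
  function(t) {
    L <- .colSums(exp(la * t) * ab, length(la), ncol(ab))
    L[L <= 0] <- .Machine$double.xmin
    sum(w * log(L))
  }
}

.sweepBranches <- function(pp, es, blen, lower = 1e-9, upper = 30,
                           tol = 1e-8) {
  n <- length(es$stationary)
  npat <- pp$npat
  dp <- .downPass(pp, es, blen, keep = TRUE)
  M <- dp$M; down <- dp$down
  up <- vector("list", pp$nNodes)
  up[[pp$root]] <- matrix(es$stationary, n, npat)

  # normalized B-projected down partial of the node below edge e
  bOf <- function(e) {
    v <- pp$edge[e, 2L]
    if (v <= pp$ntip) {
      st <- pp$tipStates[v, ]
      ok <- !is.na(st)
      if (all(ok)) es$B[, st, drop = FALSE]
      else {
        b <- matrix(rowSums(es$B), n, npat)
        b[, ok] <- es$B[, st[ok], drop = FALSE]
        b
      }
    } else es$B %*% down[[v]]
  }

  visit <- function(u) {
    kids <- pp$childEdges[[as.character(u)]]
    for (e in kids) {
      v <- pp$edge[e, 2L]
      # sibling product (W message looking down edge e)
      W <- up[[u]]
      for (f in kids) if (f != e) W <- W * M[[f]]
      sw <- .colSums(W, n, npat)
      sw[sw <= 0] <- .Machine$double.xmin
      W <- W / rep(sw, each = n)

      ab <- crossprod(es$A, W) * bOf(e)
      f1 <- .edgeObjective(es$values, ab, pp$weights)
      cur <- blen[e]
      opt <- stats::optimize(f1, c(lower, upper), maximum = TRUE, tol = tol)
      # never accept a worse point than the current length
      if (opt$objective > f1(cur)) blen[e] <<- opt$maximum

      P <- probFromEigen(es, blen[e])
      if (v > pp$ntip) {
        uv <- crossprod(P, W)
        s <- .colSums(uv, n, npat)
        s[s <= 0] <- .Machine$double.xmin
        up[[v]] <<- uv / rep(s, each = n)
        visit(v)
        # refresh this node's down partial from its children's
        # refreshed messages, then this edge's message
        kk <- pp$childEdges[[as.character(v)]]
        dv <- M[[kk[1L]]]
        for (f in kk[-1L]) dv <- dv * M[[f]]
        s <- .colSums(dv, n, npat)
        s[s <= 0] <- .Machine$double.xmin
        dv <- dv / rep(s, each = n)
        down[[v]] <<- dv
        M[[e]] <<- P %*% dv
      } else {
        M[[e]] <<- .tipMessage(P, pp$tipStates[v, ], n, npat)
      }
    }
  }
  visit(pp$root)
  blen
}
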