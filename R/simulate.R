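#' Random unrooted tree
#'
#' Uniform random unrooted binary topology (via [ape::rtopology()])
#' with branch lengths drawn independently from an exponential
#' distribution. Deterministic given `seed`; the caller's RNG state is
#' preserved.
#'
#' @param nTaxa number of taxa, `>= 2`. For `nTaxa >= 3` the tree is
#'   unrooted with `2 * nTaxa - 3` edges; `nTaxa = 2` yields the
#'   two-edge cherry ape uses to represent a single-branch tree.
#' @param seed integer seed.
#' @param meanBranchLength mean of the exponential branch-length
#'   distribution (expected substitutions per codon site under a
#'   normalized model).
#' @return an ape `phylo` object with tip labels `t1, t2, ...`.
#' @examples
#' nrow(randomTree(5, seed = 1)$edge)  # 7
#' @export
randomTree <- function(nTaxa, seed, meanBranchLength = 0.1) {
  nTaxa <- as.integer(nTaxa)
  if (nTaxa < 2L) stop("nTaxa must be >= 2", call. = FALSE)
  withPreservedSeed(seed, {
    tr <- if (nTaxa == 2L)
      ape::read.tree(text = "(t1:1,t2:1);")
    else
      ape::rtopology(nTaxa, rooted = FALSE, tip.label = paste0("t", seq_len(nTaxa)))
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / meanBranchLength)
    tr
  })
}

#' Simulate a codon alignment under a model
#'
#' Draws root states from the model's stationary distribution and
#' evolves them down every branch with the exact transition
#' probabilities `P(t) = exp(Qt)` (no discretization). Deterministic
#' given `seed`: one RNG stream, consumed edge-by-edge in the tree's
#' postorder-derived preorder, sites in order within each edge. The
#' true parameters are stored in the result's `metadata$truth`.
#'
#' With `logEvents = TRUE` the substitution history on every branch is
#' instead generated by Gillespie simulation (event-by-event; exact in
#' distribution) and the events are returned in `metadata$events`, a
#' data.frame with one row per substitution (`edge`, `site`, `time`,
#' `from`, `to`, `synonymous`).
#'
#' @param tree an ape `phylo` tree with branch lengths.
#' @param assignment a [RateClassAssignment-class].
#' @param rho,theta,pi model parameters (see [codonRateMatrix()]).
#' @param nSites number of codon sites, `>= 1`.
#' @param seed integer seed.
#' @param code a [GeneticCode-class].
#' @param normalize passed to [codonRateMatrix()] (default `TRUE`).
#' @param logEvents store full substitution histories (slower).
#' @return a [CodonAlignment-class] over the tree's tips.
#' @export
simulateAlignment <- function(tree, assignment, rho, theta = defaultTheta(),
                              pi = defaultPi(), nSites, seed,
                              code = geneticCode(), normalize = TRUE,
                              logEvents = FALSE) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  nSites <- as.integer(nSites)
  if (nSites < 1L) stop("nSites must be >= 1", call. = FALSE)
  model <- codonRateMatrix(assignment, rho, theta, pi, code, normalize = normalize)
  space <- model@stateSpace
  n <- length(space@codons)

  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  preord <- rev(seq_len(nrow(edge)))  # parents before children
  ntip <- length(tre$tip.label)
  root <- ntip + 1L

  ev <- NULL
  if (logEvents) {
    evTab <- oneStepEvents(code)
    synPair <- matrix(FALSE, n, n)
    synPair[cbind(evTab$fromState, evTab$toState)] <- evTab$synonymous
  }

  states <- withPreservedSeed(seed, {
    nodeStates <- matrix(NA_integer_, ntip + tre$Nnode, nSites)
    nodeStates[root, ] <- sample.int(n, nSites, replace = TRUE,
                                     prob = model@stationary)
    if (!logEvents) es <- eigenSystem(model)
    events <- list()
    for (e in preord) {
      u <- edge[e, 1L]; v <- edge[e, 2L]; t <- tre$edge.length[e]
      src <- nodeStates[u, ]
      if (!logEvents) {
        if (t == 0) {
          nodeStates[v, ] <- src
        } else {
          P <- probFromEigen(es, t)
          P[P < 0] <- 0  # clip eigen-roundoff noise before sampling
          out <- integer(nSites)
          for (s in unique(src)) {
            ix <- which(src == s)
            out[ix] <- sample.int(n, length(ix), replace = TRUE, prob = P[s, ])
          }
          nodeStates[v, ] <- out
        }
      } else {
        out <- integer(nSites)
        for (site in seq_len(nSites)) {
          s <- src[site]; tm <- 0
          repeat {
            rate <- -model@Q[s, s]
            if (rate <= 0) break
            tm <- tm + stats::rexp(1L, rate)
            if (tm > t) break
            probs <- model@Q[s, ]; probs[s] <- 0
            s2 <- sample.int(n, 1L, prob = probs)
            events[[length(events) + 1L]] <- data.frame(
              edge = e, site = site, time = tm,
              from = space@codons[s], to = space@codons[s2],
              synonymous = synPair[s, s2])
            s <- s2
          }
          out[site] <- s
        }
        nodeStates[v, ] <- out
      }
    }
    if (logEvents) ev <- if (length(events)) do.call(rbind, events) else
      data.frame(edge = integer(), site = integer(), time = numeric(),
                 from = character(), to = character(), synonymous = logical())
    nodeStates[seq_len(ntip), , drop = FALSE]
  })
  rownames(states) <- tre$tip.label

  truth <- list(assignment = assignment, rho = rho, theta = checkTheta(theta),
                pi = checkPi(pi), seed = as.integer(seed),
                normalize = normalize, tree = tre)
  md <- list(truth = truth)
  if (logEvents) md$events <- ev
  new("CodonAlignment", states = states, stateSpace = space, metadata = md)
}
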