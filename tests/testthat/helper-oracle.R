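# Independent oracles used to validate the implementation.

# Exhaustive-summation log-likelihood: sums the joint probability over
# every combination of internal-node states. Only feasible for tiny
# trees; deliberately shares no code with the pruning engine (uses
# transitionMatrix(), not the internal eigen cache).
bruteForceLogLik <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  P <- lapply(tree$edge.length, function(t) transitionMatrix(model, t))
  states <- aln@states[tree$tip.label, , drop = FALSE]
  npat <- ncol(states)
  n <- length(stationary(model))

  internal <- root:(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), nnode)))
  total <- numeric(npat)
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    stateOf <- function(node) {
      if (node <= ntip) states[node, ] else rep(assign_int[node - ntip], npat)
    }
    prob <- rep(stationary(model)[assign_int[1L]], npat)
    for (e in seq_len(nrow(tree$edge))) {
      u <- stateOf(tree$edge[e, 1L])
      v <- stateOf(tree$edge[e, 2L])
      pe <- P[[e]][cbind(u, v)]
      pe[is.na(pe)] <- 1  # missing tip state
      prob <- prob * pe
    }
    total <- total + prob
  }
  sum(log(total))
}

# Brute-force enumeration of one-step exchangeable residue pairs by a
# double loop over all sense-codon pairs (independent of
# oneStepEvents()).
bruteForcePairs <- function(code = geneticCode()) {
  space <- senseCodonSpace(code)
  cod <- codons(space)
  res <- stateResidues(space)
  out <- character(0)
  for (i in seq_along(cod)) for (j in seq_along(cod)) {
    if (i == j) next
    d <- sum(strsplit(cod[i], "")[[1]] != strsplit(cod[j], "")[[1]])
    if (d == 1L && res[i] != res[j])
      out <- c(out, residuePairKey(res[i], res[j]))
  }
  sort(unique(out))
}

# Random alignment over the sense codons (not model-based; for
# likelihood-identity tests only).
randomStatesAlignment <- function(taxaNames, nSitesHere, missingProb = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(codons(senseCodonSpace(geneticCode())))
  st <- matrix(sample(c(seq_len(n), NA_integer_),
                      length(taxaNames) * nSitesHere, replace = TRUE,
                      prob = c(rep((1 - missingProb) / n, n), missingProb)),
               length(taxaNames), nSitesHere,
               dimnames = list(taxaNames, NULL))
  methods::new("CodonAlignment", states = st,
               stateSpace = senseCodonSpace(geneticCode()),
               metadata = list())
}

# Random valid model parameters for property tests.
randomModelParams <- function(K = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- defaultTheta() * stats::runif(6, 0.3, 3)
  th["A:G"] <- 1
  pim <- matrix(stats::runif(12, 0.5, 2), 3, 4)
  pim <- pim / rowSums(pim)
  list(rho = stats::runif(K, 0.1, 4), theta = th, pi = pim)
}
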