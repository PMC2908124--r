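#' Read an in-frame codon alignment from FASTA
#'
#' Reads aligned nucleotide sequences and converts them to codon
#' states. Alignment length must be divisible by 3; codons containing
#' gaps or ambiguity codes become missing data; internal stop codons
#' are rejected with the offending sequence and codon site named.
#'
#' @param path FASTA file of aligned nucleotide sequences.
#' @param code a [GeneticCode-class].
#' @return a [CodonAlignment-class].
#' @export
readCodonFasta <- function(path, code = geneticCode()) {
  seqs <- Biostrings::readDNAStringSet(path)
  aln <- codonAlignment(stats::setNames(as.character(seqs), names(seqs)),
                        code = code, metadata = list(source = path))
  aln
}

#' Write a codon alignment as FASTA
#'
#' @param aln a [CodonAlignment-class].
#' @param path output file; missing codons are written as `---`.
#' @return `path`, invisibly.
#' @export
writeCodonFasta <- function(aln, path) {
  seqs <- Biostrings::DNAStringSet(alignmentSequences(aln))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @param taxa optional character vector (e.g. `taxa(aln)`): the tree's
#'   tip labels must match it exactly, otherwise an error lists the
#'   mismatches.
#' @param requireBranchLengths error when branch lengths are absent
#'   (default `TRUE`); with `FALSE`, absent lengths are initialized to
#'   `initBranchLength`.
#' @param initBranchLength value used when lengths are absent and not
#'   required.
#' @return an ape `phylo` object.
#' @export
readNewick <- function(path, taxa = NULL, requireBranchLengths = TRUE,
                       initBranchLength = 0.1) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file ", path, call. = FALSE)
  if (is.null(tr$edge.length)) {
    if (requireBranchLengths)
      stop("tree in ", path, " has no branch lengths", call. = FALSE)
    tr$edge.length <- rep(initBranchLength, nrow(tr$edge))
  }
  if (!is.null(taxa)) {
    onlyTree <- setdiff(tr$tip.label, taxa)
    onlyAln <- setdiff(taxa, tr$tip.label)
    if (length(onlyTree) || length(onlyAln))
      stop("tree/alignment taxon mismatch; only in tree: ",
           paste(onlyTree, collapse = ", "), "; only in alignment: ",
           paste(onlyAln, collapse = ", "), call. = FALSE)
  }
  tr
}

.fitToList <- function(fit) {
  asn <- fit@modelDescriptor$assignment
  list(log_likelihood = fit@logLik,
       n_free_parameters = fit@nFreeParameters,
       rate_parameters = fit@rateParameterCount,
       converged = fit@converged,
       boundary = fit@boundary,
       model = list(
         n_classes = if (!is.null(asn)) asn@nClasses,
         effective_classes = if (!is.null(asn)) effectiveClasses(asn),
         classes = if (!is.null(asn)) as.list(asn@classOf - 1L),
         bias_model = fit@modelDescriptor$biasModel,
         freq_policy = fit@modelDescriptor$freqPolicy),
       estimates = list(
         rho = as.list(fit@estimates$rho),
         theta = as.list(fit@estimates$theta),
         pi = apply(fit@estimates$pi, 1L, as.list),
         branch_lengths = as.list(fit@estimates$branchLengths)),
       tree = ape::write.tree(fit@tree))
}

#' Serialize a fit as JSON
#'
#' @param fit a [FitResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  jsonlite::write_json(.fitToList(fit), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write benchmark outputs to a directory
#'
#' Writes `table1.tsv` (significance counts), `table2.tsv` (BIC
#' comparison) and `replicates.json` (one record per ensemble
#' replicate: seed, log-likelihood, df, p-value, BIC, convergence)
#' under `dir`, creating it if needed.
#'
#' @param entries as for [summarizeBenchmark()].
#' @param dir output directory.
#' @return the list returned by [summarizeBenchmark()], invisibly.
#' @export
writeBenchmarkOutputs <- function(entries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- summarizeBenchmark(entries)
  utils::write.table(tabs$significance, file.path(dir, "table1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tabs$bicTable, file.path(dir, "table2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- lapply(names(entries), function(nm) {
    en <- entries[[nm]]
    lapply(en$ensembles, function(ens) {
      reps <- lapply(seq_len(ens@nReplicates), function(r) {
        f <- ens@fits[[r]]; cmp <- ens@comparisons[[r]]
        list(seed = ens@seeds[r],
             log_likelihood = f@logLik,
             converged = f@converged,
             df = if (!is.null(cmp)) cmp@df,
             lr_statistic = if (!is.null(cmp)) cmp@lrStatistic,
             p_value = if (!is.null(cmp)) cmp@pValue,
             bic = if (f@converged) bic(f, ens@nSites))
      })
      list(alignment = nm, K = ens@K, alpha = ens@alpha,
           sr_log_likelihood = ens@srFit@logLik,
           sr_bic = bic(ens@srFit, ens@nSites),
           replicates = reps)
    })
  })
  jsonlite::write_json(log, file.path(dir, "replicates.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tabs)
}
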