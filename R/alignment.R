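#' Construct a codon alignment from nucleotide sequences
#'
#' Splits aligned, in-frame nucleotide sequences into codons and maps
#' them to sense-codon state indices. Codons containing gaps or
#' ambiguity codes become missing data (`NA`); stop codons are
#' rejected with the offending sequence and codon position named.
#'
#' @param sequences named character vector of aligned nucleotide
#'   sequences (equal lengths, length divisible by 3).
#' @param code a [GeneticCode-class].
#' @param metadata optional list of annotations.
#' @return a [CodonAlignment-class].
#' @examples
#' codonAlignment(c(s1 = "ATGGGG", s2 = "AT-GGG"))
#' @export
codonAlignment <- function(sequences, code = geneticCode(), metadata = list()) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names", call. = FALSE)
  w <- unique(nchar(sequences))
  if (length(w) != 1L)
    stop("ragged alignment: sequence lengths ", paste(sort(w), collapse = ", "),
         call. = FALSE)
  if (w %% 3L != 0L)
    stop("alignment length ", w, " is not divisible by 3 (frame violation)",
         call. = FALSE)
  nSites <- w %/% 3L
  space <- senseCodonSpace(code)
  stops <- names(code@codonToResidue)[code@codonToResidue == "*"]

  starts <- seq(1L, w, by = 3L)
  states <- matrix(NA_integer_, length(sequences), nSites,
                   dimnames = list(names(sequences), NULL))
  for (i in seq_along(sequences)) {
    seqUp <- chartr("u", "T", toupper(sequences[[i]]))
    cods <- substring(seqUp, starts, starts + 2L)
    bad <- which(cods %in% stops)
    if (length(bad))
      stop("stop codon ", cods[bad[1L]], " in sequence '",
           names(sequences)[i], "' at codon site ", bad[1L], call. = FALSE)
    states[i, ] <- codonIndex(space, cods)
  }
  new("CodonAlignment", states = states, stateSpace = space,
      metadata = metadata)
}

#' @describeIn codonAlignment number of taxa.
#' @param x a [CodonAlignment-class].
#' @export
setMethod("nTaxa", "CodonAlignment", function(x) nrow(x@states))

#' @describeIn codonAlignment number of codon sites.
#' @export
setMethod("nSites", "CodonAlignment", function(x) ncol(x@states))

#' @describeIn codonAlignment taxon labels.
#' @export
setMethod("taxa", "CodonAlignment", function(x) rownames(x@states))

#' @describeIn codonAlignment codons of the underlying state space.
#' @export
setMethod("codons", "CodonAlignment", function(x) x@stateSpace@codons)

setMethod("show", "CodonAlignment", function(object) {
  miss <- mean(is.na(object@states))
  cat("CodonAlignment: ", nrow(object@states), " taxa x ",
      ncol(object@states), " codon sites (",
      format(100 * miss, digits = 3), "% missing)\n", sep = "")
})

#' Decode alignment states to nucleotide sequences
#'
#' @param aln a [CodonAlignment-class].
#' @param missing string used for missing codons (default `"---"`).
#' @return named character vector of nucleotide sequences.
#' @export
alignmentSequences <- function(aln, missing = "---") {
  cod <- codons(aln)
  apply(aln@states, 1L, function(st) {
    s <- cod[st]
    s[is.na(s)] <- missing
    paste(s, collapse = "")
  })
}

#' Observed position-specific nucleotide frequencies
#'
#' Empirical 3 x 4 positional nucleotide proportions over the
#' non-missing codons of an alignment; used to initialize (or fix,
#' under `freqPolicy = "observed"`) the frequency parameters.
#'
#' @param aln a [CodonAlignment-class].
#' @param pseudocount added to every cell so all frequencies are
#'   positive (default 0.5).
#' @return 3 x 4 matrix, rows summing to 1.
#' @export
observedPositionalFreqs <- function(aln, pseudocount = 0.5) {
  cod <- codons(aln)[aln@states[!is.na(aln@states)]]
  mat <- do.call(rbind, strsplit(cod, ""))
  counts <- matrix(pseudocount, 3, 4,
                   dimnames = list(paste0("pos", 1:3), NUCLEOTIDES))
  for (k in 1:3) {
    tb <- table(factor(mat[, k], levels = NUCLEOTIDES))
    counts[k, ] <- counts[k, ] + as.numeric(tb)
  }
  counts / rowSums(counts)
}
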