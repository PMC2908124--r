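NUCLEOTIDES <- c("A", "C", "G", "T")

# memo cache for per-code derived objects (state space, events, pairs)
.gcCache <- new.env(parent = emptyenv())

.cached <- function(kind, code, builder) {
  key <- paste0(kind, ":", code@tableId)
  if (!exists(key, envir = .gcCache, inherits = FALSE))
    assign(key, builder(), envir = .gcCache)
  get(key, envir = .gcCache, inherits = FALSE)
}

#' Build a genetic code
#'
#' Constructs a [GeneticCode-class] from a standard NCBI translation
#' table (via [Biostrings::getGeneticCode()]). Codons are ordered
#' lexicographically with `A < C < G < T`.
#'
#' @param tableId translation-table identifier: `"universal"`,
#'   `"standard"` or an NCBI table id such as `"1"` (all equivalent to
#'   the standard code), or any other id accepted by
#'   [Biostrings::getGeneticCode()] (e.g. `"2"` for the vertebrate
#'   mitochondrial code).
#' @return a [GeneticCode-class].
#' @examples
#' gc <- geneticCode()
#' gc@codonToResidue[["TGG"]]  # "W"
#' sum(gc@codonToResidue == "*")  # 3 stop codons
#' @export
geneticCode <- function(tableId = "universal") {
  id <- as.character(tableId)
  if (id %in% c("universal", "standard")) id <- "1"
  tab <- tryCatch(Biostrings::getGeneticCode(id),
    error = function(e) stop("unsupported translation table '", tableId, "'",
                             call. = FALSE))
  codons <- sort(names(tab))  # lexicographic, A < C < G < T
  new("GeneticCode", tableId = as.character(tableId),
      codonToResidue = tab[codons])
}

#' @describeIn geneticCode all 64 codons of a code, in state order.
#' @param x a [GeneticCode-class].
#' @export
setMethod("codons", "GeneticCode", function(x) names(x@codonToResidue))

#' Sense-codon state space
#'
#' Drops the stop codons of a genetic code and fixes the deterministic
#' lexicographic state ordering used by every matrix and vector in the
#' package. Under the universal code the space has 61 states and codon
#' `AAA` has index 1.
#'
#' @param code a [GeneticCode-class].
#' @return a [CodonStateSpace-class].
#' @examples
#' ss <- senseCodonSpace(geneticCode())
#' length(codons(ss))  # 61
#' @export
senseCodonSpace <- function(code = geneticCode()) {
  stopifnot(is(code, "GeneticCode"))
  .cached("space", code, function() {
    sense <- names(code@codonToResidue)[code@codonToResidue != "*"]
    new("CodonStateSpace", codons = sort(sense), geneticCode = code)
  })
}

#' @describeIn senseCodonSpace sense codons in state order.
#' @param x a [CodonStateSpace-class].
#' @export
setMethod("codons", "CodonStateSpace", function(x) x@codons)

#' Integer state index of codons
#'
#' @param space a [CodonStateSpace-class].
#' @param codon character vector of codons.
#' @return integer indices into `codons(space)` (`NA` for codons not in
#'   the space, e.g. stops or ambiguous triplets).
#' @export
codonIndex <- function(space, codon) {
  match(codon, space@codons)
}

#' Residue encoded by each state
#'
#' @param space a [CodonStateSpace-class].
#' @return character vector of one-letter residue codes, in state order.
#' @export
stateResidues <- function(space) {
  unname(space@geneticCode@codonToResidue[space@codons])
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (table ", object@tableId, "): ",
      sum(object@codonToResidue != "*"), " sense codons, ",
      sum(object@codonToResidue == "*"), " stops\n", sep = "")
})

setMethod("show", "CodonStateSpace", function(object) {
  cat("CodonStateSpace:", length(object@codons), "sense codons (table",
      object@geneticCode@tableId, ")\n")
})

#' Single-nucleotide substitution events between sense codons
#'
#' Enumerates every ordered pair of sense codons that differ at exactly
#' one nucleotide position -- the only instantaneous changes the model
#' family allows. Each event is annotated with the changed codon
#' position, the source/target nucleotides and whether the change is
#' synonymous. The relation is symmetric: the event `i -> j` is listed
#' iff `j -> i` is.
#'
#' @param code a [GeneticCode-class].
#' @return a data.frame with columns `from`, `to` (codons), `fromState`,
#'   `toState` (integer indices), `position` (1, 2 or 3), `fromNuc`,
#'   `toNuc`, `fromResidue`, `toResidue`, `synonymous` (logical).
#' @examples
#' ev <- oneStepEvents(geneticCode())
#' subset(ev, from == "AAA" & to == "AAG")$synonymous  # TRUE (Lys -> Lys)
#' @export
oneStepEvents <- function(code = geneticCode()) {
  .cached("events", code, function() .buildOneStepEvents(code))
}

.buildOneStepEvents <- function(code) {
  space <- senseCodonSpace(code)
  cod <- space@codons
  res <- stateResidues(space)
  n <- length(cod)
  mat <- do.call(rbind, strsplit(cod, ""))
  out <- vector("list", 3L)
  for (pos in 1:3) {
    same <- apply(mat[, -pos, drop = FALSE], 1L, paste, collapse = "")
    grp <- split(seq_len(n), same)
    pieces <- lapply(grp, function(ix) {
      if (length(ix) < 2L) return(NULL)
      pr <- expand.grid(i = ix, j = ix)
      pr <- pr[pr$i != pr$j, , drop = FALSE]
      pr
    })
    pr <- do.call(rbind, pieces)
    out[[pos]] <- data.frame(
      from = cod[pr$i], to = cod[pr$j],
      fromState = pr$i, toState = pr$j,
      position = pos,
      fromNuc = mat[pr$i, pos], toNuc = mat[pr$j, pos],
      fromResidue = res[pr$i], toResidue = res[pr$j],
      synonymous = res[pr$i] == res[pr$j],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$fromState, ev$toState), ]
  rownames(ev) <- NULL
  ev
}

#' Residue-pair key
#'
#' Canonical key for an unordered pair of one-letter residue codes:
#' the two codes sorted alphabetically and joined with `":"`
#' (`"A:C"`). Used to index rate-class assignments.
#'
#' @param a,b character vectors of one-letter residue codes.
#' @return character vector of keys.
#' @export
residuePairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' One-step exchangeable residue pairs
#'
#' The set of unordered amino-acid pairs reachable by a single
#' nucleotide substitution between sense codons. Under the universal
#' code there are exactly 75 such pairs (out of the 190 unordered pairs
#' of 20 residues); these are the units to which exchangeability
#' classes are assigned.
#'
#' @param code a [GeneticCode-class].
#' @return sorted character vector of residue-pair keys (see
#'   [residuePairKey()]).
#' @examples
#' pr <- exchangeablePairs(geneticCode())
#' length(pr)           # 75
#' "R:W" %in% pr        # TRUE: TGG (Trp) -> CGG (Arg) is one step
#' @export
exchangeablePairs <- function(code = geneticCode()) {
  .cached("pairs", code, function() {
    ev <- oneStepEvents(code)
    ns <- ev[!ev$synonymous, ]
    sort(unique(residuePairKey(ns$fromResidue, ns$toResidue)))
  })
}
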