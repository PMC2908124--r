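#' Codon states of an object
#'
#' @param x an object with an associated codon state space.
#' @return character vector of codons in state order.
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))

#' Number of taxa
#' @param x an alignment.
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' Number of codon sites
#' @param x an alignment.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Taxon labels
#' @param x an alignment.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Number of rate classes
#' @param x a rate-class assignment or ensemble result.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' Class label of each one-step residue pair
#' @param x a rate-class assignment.
#' @return named integer vector over the residue-pair keys.
#' @export
setGeneric("classOf", function(x) standardGeneric("classOf"))

#' Stationary distribution of a rate matrix
#' @param x a [CodonRateMatrix-class].
#' @return named numeric probability vector over the sense codons.
#' @export
setGeneric("stationary", function(x) standardGeneric("stationary"))

#' Model parameter estimates of a fit
#' @param x a [FitResult-class].
#' @return list with `branchLengths`, `theta`, `pi`, `rho`.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' Total free-parameter count of a fit
#' @param x a [FitResult-class].
#' @export
setGeneric("nFreeParameters", function(x) standardGeneric("nFreeParameters"))

#' Convergence flag of a fit
#' @param x a [FitResult-class].
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
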