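#' Rate-class assignments over the one-step residue pairs
#'
#' The model family is indexed by a partition of the one-step
#' exchangeable residue pairs (75 under the universal code) into K
#' exchangeability classes, each class sharing one non-synonymous rate:
#'
#' * `srAssignment()` -- the single-rate (SR) model: K = 1, all pairs
#'   in one class, whose rate is the classical omega (dN/dS).
#' * `revAssignment()` -- the codon general time-reversible (REV)
#'   model: K = 75, each pair its own class.
#' * `randomAssignment()` -- each pair assigned independently and
#'   uniformly to one of K classes, so classes are balanced on
#'   average; some classes may come out empty, which reduces the
#'   model's effective rate-parameter count (see
#'   [effectiveClasses()]).
#'
#' @param code a [GeneticCode-class].
#' @param K integer number of classes, `1 <= K <=` number of pairs.
#' @param seed integer; the assignment is a deterministic function of
#'   `(K, seed)` and the caller's RNG state is left untouched.
#' @return a [RateClassAssignment-class].
#' @examples
#' nClasses(srAssignment())                     # 1
#' nClasses(revAssignment())                    # 75
#' a <- randomAssignment(5, seed = 42)
#' identical(a, randomAssignment(5, seed = 42)) # TRUE
#' @name assignments
NULL

#' @rdname assignments
#' @export
srAssignment <- function(code = geneticCode()) {
  pairs <- exchangeablePairs(code)
  cl <- rep(1L, length(pairs))
  names(cl) <- pairs
  new("RateClassAssignment", nClasses = 1L, classOf = cl)
}

#' @rdname assignments
#' @export
revAssignment <- function(code = geneticCode()) {
  pairs <- exchangeablePairs(code)
  cl <- seq_along(pairs)
  names(cl) <- pairs
  new("RateClassAssignment", nClasses = length(pairs), classOf = cl)
}

#' @rdname assignments
#' @export
randomAssignment <- function(K, seed, code = geneticCode()) {
  pairs <- exchangeablePairs(code)
  K <- as.integer(K)
  if (K < 1L || K > length(pairs))
    stop("K must lie in 1..", length(pairs), call. = FALSE)
  cl <- withPreservedSeed(seed, sample.int(K, length(pairs), replace = TRUE))
  names(cl) <- pairs
  new("RateClassAssignment", nClasses = K, classOf = cl)
}

# Run expr under set.seed(seed) and restore the caller's RNG state.
withPreservedSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Build an assignment from explicit class labels
#'
#' @param classOf named integer vector over residue-pair keys (`"A:C"`
#'   style, see [residuePairKey()]); labels in `1..K`.
#' @param nClasses K; defaults to `max(classOf)`.
#' @param code a [GeneticCode-class] whose pair set must be covered
#'   exactly.
#' @return a [RateClassAssignment-class].
#' @export
rateClassAssignment <- function(classOf, nClasses = max(classOf),
                                code = geneticCode()) {
  pairs <- exchangeablePairs(code)
  if (!setequal(names(classOf), pairs))
    stop("classOf must assign exactly the one-step residue pairs of the code",
         call. = FALSE)
  cl <- as.integer(classOf[pairs])
  names(cl) <- pairs
  new("RateClassAssignment", nClasses = as.integer(nClasses), classOf = cl)
}

#' @describeIn assignments number of classes K of an assignment.
#' @param x a [RateClassAssignment-class].
#' @export
setMethod("nClasses", "RateClassAssignment", function(x) x@nClasses)

#' @describeIn assignments named class labels of an assignment.
#' @export
setMethod("classOf", "RateClassAssignment", function(x) x@classOf)

#' Effective (non-empty) class count
#'
#' Classes that receive no pair under a random assignment contribute no
#' estimable rate; all degrees-of-freedom and BIC accounting uses this
#' effective count.
#'
#' @param assignment a [RateClassAssignment-class].
#' @return integer number of non-empty classes.
#' @export
effectiveClasses <- function(assignment) {
  length(unique(assignment@classOf))
}

setMethod("show", "RateClassAssignment", function(object) {
  eff <- effectiveClasses(object)
  cat("RateClassAssignment: ", length(object@classOf), " residue pairs in ",
      object@nClasses, " classes (", eff, " non-empty)\n", sep = "")
  occ <- table(factor(object@classOf, levels = seq_len(object@nClasses)))
  cat("  class sizes:", paste(as.integer(occ), collapse = " "), "\n")
})

#' Serialize / deserialize assignments as JSON
#'
#' The on-disk form uses 0-based class labels:
#' `{"n_classes": K, "classes": {"A:C": 0, ...}}`.
#'
#' @param assignment a [RateClassAssignment-class].
#' @param path file path.
#' @param code a [GeneticCode-class] used to validate the pair set on
#'   read.
#' @return `writeAssignment` returns `path` invisibly;
#'   `readAssignment` returns a [RateClassAssignment-class].
#' @export
writeAssignment <- function(assignment, path) {
  obj <- list(n_classes = assignment@nClasses,
              classes = as.list(assignment@classOf - 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeAssignment
#' @export
readAssignment <- function(path, code = geneticCode()) {
  obj <- jsonlite::read_json(path)
  cl <- vapply(obj$classes, function(x) as.integer(x) + 1L, integer(1))
  rateClassAssignment(cl, nClasses = as.integer(obj$n_classes), code = code)
}

#' Is one assignment nested in another?
#'
#' A null assignment is nested in an alternative when the alternative's
#' partition refines it: every alternative class lies wholly inside one
#' null class. SR is nested in every assignment; every assignment is
#' nested in REV.
#'
#' @param null,alt [RateClassAssignment-class] objects over the same
#'   pair set.
#' @return logical.
#' @export
isNestedAssignment <- function(null, alt) {
  if (!identical(names(null@classOf), names(alt@classOf))) return(FALSE)
  all(vapply(split(null@classOf, alt@classOf),
             function(v) length(unique(v)) == 1L, logical(1)))
}
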