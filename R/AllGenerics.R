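#' Accessors for the package's S4 containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return `lociNames`: character vector of locus names. `sampleLabels`:
#'   character vector of the distinct sample labels in annotation order.
#'   `indIDs`: individual identifiers. `sampleAnnotation`: the annotation
#'   data.frame. `nIndividuals`: integer count (optionally per sample).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("indIDs", function(x) standardGeneric("indIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleAnnotation", function(x) standardGeneric("sampleAnnotation"))
#' @rdname accessors
#' @param sample optional sample label to count individuals of.
#' @export
setGeneric("nIndividuals", function(x, sample = NULL) standardGeneric("nIndividuals"))

#' @rdname accessors
setMethod("lociNames", "GenotypeTable", function(x) x@loci)
#' @rdname accessors
setMethod("sampleLabels", "GenotypeTable", function(x) x@annotation$label)
#' @rdname accessors
setMethod("indIDs", "GenotypeTable", function(x) x@ids)
#' @rdname accessors
setMethod("sampleAnnotation", "GenotypeTable", function(x) x@annotation)
#' @rdname accessors
setMethod("nIndividuals", "GenotypeTable", function(x, sample = NULL) {
  if (is.null(sample)) length(x@ids) else sum(x@pop == sample)
})

#' Point estimate and bounds of an NeEstimate
#'
#' @param x an [NeEstimate-class].
#' @return `nePoint`: numeric scalar (possibly `Inf`). `neBounds`: numeric
#'   length-2 vector `c(lower, upper)`.
#' @export
nePoint <- function(x) {
  stopifnot(is(x, "NeEstimate"))
  x@point
}

#' @rdname nePoint
#' @export
neBounds <- function(x) {
  stopifnot(is(x, "NeEstimate"))
  c(lower = x@lower, upper = x@upper)
}

#' Posterior mode and highest-density intervals of a PosteriorResult
#'
#' @param x a [PosteriorResult-class].
#' @param level HDI mass (must be one of the levels the result was built with).
#' @return `posteriorMode`: named numeric vector of modes on the natural
#'   scale. `posteriorHdi`: parameters x 2 matrix of interval bounds.
#' @export
posteriorMode <- function(x) {
  stopifnot(is(x, "PosteriorResult"))
  x@mode
}

#' @rdname posteriorMode
#' @export
posteriorHdi <- function(x, level = 0.95) {
  stopifnot(is(x, "PosteriorResult"))
  key <- as.character(level)
  if (!key %in% names(x@hdi))
    stop("no HDI at level ", level, "; available: ",
         paste(names(x@hdi), collapse = ", "))
  x@hdi[[key]]
}

#' Subset a GenotypeTable to one population sample
#'
#' @param x a [GenotypeTable-class].
#' @param sample a sample label present in the annotation.
#' @return A [GenotypeTable-class] restricted to the individuals of that
#'   sample (annotation keeps only that row).
#' @export
bySample <- function(x, sample) {
  stopifnot(is(x, "GenotypeTable"))
  if (!sample %in% x@annotation$label) stop("unknown sample label: ", sample)
  keep <- x@pop == sample
  GenotypeTable(x@a1[keep, , drop = FALSE], x@a2[keep, , drop = FALSE],
                loci = x@loci, ids = x@ids[keep], pop = x@pop[keep],
                annotation = x@annotation[x@annotation$label == sample, ,
                                          drop = FALSE])
}
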