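#' Accessors for CactaScan containers
#'
#' `orientation()`, `inwardSequence()`, `tsdCandidate()` and
#' `seedVariant()` extract the per-occurrence annotation of a
#' [TirOccurrences-class] object; `elementTsd()`, `elementSpan()`,
#' `leftTir()` and `rightTir()` the per-call annotation of a
#' [CactaCalls-class] object; `simGenome()`, `simTruth()` and `simConfig()`
#' the slots of a [CactaSimulation-class].
#'
#' @param x the container.
#' @return A vector (or, for `simGenome()`/`simTruth()`, the stored
#'   `DNAStringSet`/`GRanges`) parallel to `x`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setGeneric("inwardSequence", function(x) standardGeneric("inwardSequence"))
#' @rdname accessors
#' @export
setGeneric("tsdCandidate", function(x) standardGeneric("tsdCandidate"))
#' @rdname accessors
#' @export
setGeneric("seedVariant", function(x) standardGeneric("seedVariant"))
#' @rdname accessors
#' @export
setGeneric("elementTsd", function(x) standardGeneric("elementTsd"))
#' @rdname accessors
#' @export
setGeneric("elementSpan", function(x) standardGeneric("elementSpan"))
#' @rdname accessors
#' @export
setGeneric("leftTir", function(x) standardGeneric("leftTir"))
#' @rdname accessors
#' @export
setGeneric("rightTir", function(x) standardGeneric("rightTir"))
#' @rdname accessors
#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname accessors
setMethod("orientation", "TirOccurrences",
          function(x) mcols(x)$orientation)
#' @rdname accessors
setMethod("inwardSequence", "TirOccurrences",
          function(x) mcols(x)$inward)
#' @rdname accessors
setMethod("tsdCandidate", "TirOccurrences",
          function(x) mcols(x)$tsd)
#' @rdname accessors
setMethod("seedVariant", "TirOccurrences",
          function(x) mcols(x)$seedVariant)
#' @rdname accessors
setMethod("elementTsd", "CactaCalls", function(x) mcols(x)$tsd)
#' @rdname accessors
setMethod("elementSpan", "CactaCalls", function(x) mcols(x)$span)
#' @rdname accessors
setMethod("leftTir", "CactaCalls", function(x) mcols(x)$leftTir)
#' @rdname accessors
setMethod("rightTir", "CactaCalls", function(x) mcols(x)$rightTir)
#' @rdname accessors
setMethod("simGenome", "CactaSimulation", function(x) x@genome)
#' @rdname accessors
setMethod("simTruth", "CactaSimulation", function(x) x@truth)
#' @rdname accessors
setMethod("simConfig", "CactaSimulation", function(x) x@config)
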