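#' @include AllClasses.R
NULL

#' Accessor generics for chromTF classes
#'
#' Small family of accessors shared by the core classes:
#' \code{states()} returns the ordered state labels of a segmentation or
#' emission matrix, \code{chromSizes()} the named chromosome lengths,
#' \code{binSize()} the segmentation grid in bp, \code{marks()} the
#' mark/variant names of an emission matrix, \code{emissions()} the numeric
#' state-by-mark probability matrix, \code{geneIds()}, \code{tss()},
#' \code{tts()} and \code{featureClass()} the per-gene fields of a
#' [GeneModelSet], and \code{tfId()} / \code{assayType()} the identity of a
#' [PeakSet]. TSS/TTS coordinates are reported on the 0-based half-open
#' scale used by BED (TSS = interval start for `+` genes, interval end for
#' `-` genes).
#'
#' @param x One of the chromTF core objects.
#' @return An atomic vector or matrix; see the individual descriptions.
#' @name chromTF-accessors
#' @aliases states chromSizes binSize marks emissions geneIds tss tts
#'   featureClass tfId assayType
NULL

#' @rdname chromTF-accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname chromTF-accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname chromTF-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname chromTF-accessors
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))

#' @rdname chromTF-accessors
#' @export
setGeneric("emissions", function(x) standardGeneric("emissions"))

#' @rdname chromTF-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname chromTF-accessors
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname chromTF-accessors
#' @export
setGeneric("tts", function(x) standardGeneric("tts"))

#' @rdname chromTF-accessors
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))

#' @rdname chromTF-accessors
#' @export
setGeneric("tfId", function(x) standardGeneric("tfId"))

#' @rdname chromTF-accessors
#' @export
setGeneric("assayType", function(x) standardGeneric("assayType"))
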