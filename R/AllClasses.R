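#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
NULL

## Reserved label for bins the upstream segmentation left uncalled.  It is
## carried in the interval labels but never in states(), and is excluded
## from every denominator unless a function documents otherwise.
UNASSIGNED <- "unassigned"

#' @export
unassignedLabel <- function() UNASSIGNED

#' StateSegmentation: a genome-tiling chromatin-state map
#'
#' Holds a ChromHMM-style segmentation: labelled intervals on a fixed bin
#' grid (200 bp by default) that tile every chromosome completely.  Gaps in
#' the input are filled with the reserved label `"unassigned"` at read time,
#' so validity can insist on full coverage.
#'
#' @slot ranges A [GenomicRanges::GRanges] sorted and disjoint, with a
#'   character metadata column `state`; together the intervals cover
#'   `[0, chromSize)` of every chromosome.
#' @slot states Ordered character vector of real state labels (never
#'   includes `"unassigned"`).
#' @slot chromSizes Named numeric vector of chromosome lengths in bp.
#' @slot binSize Segmentation grid in bp.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), state = "E1")
#' seg <- StateSegmentation(gr, chromSizes = c(chr1 = 1000), binSize = 200)
#' genomeCoverage(seg)
#' @export
setClass("StateSegmentation",
  representation(
    ranges = "GRanges",
    states = "character",
    chromSizes = "numeric",
    binSize = "numeric"
  )
)

setValidity("StateSegmentation", function(object) {
  gr <- object@ranges
  msg <- character()
  if (length(gr) == 0L) msg <- c(msg, "segmentation is empty")
  if (is.null(gr$state)) msg <- c(msg, "ranges must carry a 'state' column")
  if (is.null(names(object@chromSizes)) || any(!nzchar(names(object@chromSizes))))
    msg <- c(msg, "chromSizes must be named")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (length(msg)) return(msg)
  extra <- setdiff(setdiff(unique(gr$state), UNASSIGNED), object@states)
  if (length(extra))
    msg <- c(msg, paste0("interval states missing from states slot: ",
                         paste(extra, collapse = ", ")))
  for (chr in names(object@chromSizes)) {
    g <- gr[as.character(seqnames(gr)) == chr]
    if (length(g) == 0L) {
      msg <- c(msg, paste0("chromosome ", chr, " has no intervals"))
      next
    }
    o <- order(GenomicRanges::start(g))
    s0 <- GenomicRanges::start(g)[o] - 1L  # 0-based starts
    e0 <- GenomicRanges::end(g)[o]        # 0-based exclusive ends
    if (any(s0[-1] != e0[-length(e0)]))
      msg <- c(msg, paste0("intervals on ", chr, " overlap or leave gaps"))
    if (s0[1] != 0 || e0[length(e0)] != object@chromSizes[[chr]])
      msg <- c(msg, paste0("intervals on ", chr, " do not span [0, chromSize)"))
    w <- e0 - s0
    if (any(w[-length(w)] %% object@binSize != 0))
      msg <- c(msg, paste0("non-terminal interval on ", chr,
                           " is not a multiple of binSize"))
  }
  if (length(msg)) msg else TRUE
})

#' @param ranges GRanges with a `state` metadata column (1-based, as GRanges
#'   always is; BED input is converted on read).
#' @param states Ordered state labels; defaults to the sorted unique labels.
#' @param chromSizes Named vector of chromosome lengths; defaults to the
#'   right-most interval end per chromosome.
#' @param binSize Grid size in bp (default 200).
#' @rdname StateSegmentation-class
#' @export
StateSegmentation <- function(ranges, states = NULL, chromSizes = NULL,
                              binSize = 200) {
  if (is.null(ranges$state))
    stop("'ranges' must carry a 'state' metadata column")
  ranges$state <- as.character(ranges$state)
  ranges <- GenomicRanges::sort(ranges, ignore.strand = TRUE)
  if (is.null(chromSizes)) {
    ends <- tapply(GenomicRanges::end(ranges),
                   as.character(seqnames(ranges)), max)
    chromSizes <- stats::setNames(as.numeric(ends), names(ends))
  }
  chromSizes <- chromSizes[sort(names(chromSizes))]
  if (is.null(states))
    states <- sort(setdiff(unique(ranges$state), UNASSIGNED))
  GenomeInfoDb::seqlevels(ranges) <- names(chromSizes)
  seqlengths(ranges) <- chromSizes
  new("StateSegmentation", ranges = ranges, states = states,
      chromSizes = chromSizes, binSize = binSize)
}

#' EmissionMatrix: per-state emission probabilities
#'
#' State-by-mark matrix of emission probabilities from a multivariate HMM
#' segmentation model; all entries lie in `[0, 1]`.
#'
#' @slot p Numeric matrix, rows = states, columns = marks/variants.
#' @examples
#' em <- EmissionMatrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2,
#'   dimnames = list(c("H1", "E1"), c("H3K9me2", "H3K36me3"))))
#' marks(em)
#' @export
setClass("EmissionMatrix", representation(p = "matrix"))

setValidity("EmissionMatrix", function(object) {
  p <- object@p
  msg <- character()
  if (!is.numeric(p)) msg <- c(msg, "emission matrix must be numeric")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "emission matrix needs state row names and mark column names")
  else {
    if (anyDuplicated(rownames(p))) msg <- c(msg, "duplicate state names")
    if (anyDuplicated(colnames(p))) msg <- c(msg, "duplicate mark names")
  }
  if (is.numeric(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "emission probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param p State-by-mark numeric matrix with dimnames.
#' @rdname EmissionMatrix-class
#' @export
EmissionMatrix <- function(p) new("EmissionMatrix", p = as.matrix(p))

#' GeneModelSet: gene records with strand-aware TSS/TTS
#'
#' Gene-level annotation with one interval per gene, a unique id, a feature
#' class (`protein_coding`, `TE` or `other`) and strand.  The TSS is the
#' interval start (0-based) for `+` genes and the interval end for `-`
#' genes; the TTS is the opposite boundary.
#'
#' @slot ranges GRanges with metadata columns `gene_id` and `feature_class`;
#'   strand is `+` or `-`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'   strand = "+", gene_id = "g1", feature_class = "protein_coding")
#' gm <- GeneModelSet(gr)
#' tss(gm)
#' @export
setClass("GeneModelSet", representation(ranges = "GRanges"))

setValidity("GeneModelSet", function(object) {
  gr <- object@ranges
  msg <- character()
  if (is.null(gr$gene_id)) msg <- c(msg, "ranges must carry 'gene_id'")
  else if (anyDuplicated(gr$gene_id)) msg <- c(msg, "gene ids must be unique")
  if (is.null(gr$feature_class)) msg <- c(msg, "ranges must carry 'feature_class'")
  else if (!all(gr$feature_class %in% c("protein_coding", "TE", "other")))
    msg <- c(msg, "feature_class must be protein_coding, TE or other")
  if (length(gr) && any(as.character(GenomicRanges::strand(gr)) == "*"))
    msg <- c(msg, "every gene needs a '+' or '-' strand")
  if (length(msg)) msg else TRUE
})

#' @param ranges Stranded GRanges with `gene_id` and `feature_class` columns.
#' @rdname GeneModelSet-class
#' @export
GeneModelSet <- function(ranges) {
  ranges$gene_id <- as.character(ranges$gene_id)
  ranges$feature_class <- as.character(ranges$feature_class)
  new("GeneModelSet", ranges = ranges)
}

#' PeakSet: one TF experiment's binding intervals
#'
#' Peaks of a single transcription-factor binding experiment, tagged with
#' the assay that produced them (`chip`, `dap` or `pwm`).  Peaks may carry a
#' `score` and a `summit` (offset from the peak start; `NA` if absent).
#'
#' @slot tfId Character scalar, the TF/experiment identifier.
#' @slot assay One of `"chip"`, `"dap"`, `"pwm"`.
#' @slot ranges GRanges of peaks, sorted.
#' @examples
#' ps <- PeakSet("TF1", "chip",
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400)))
#' peakCenters(ps)
#' @export
setClass("PeakSet",
  representation(tfId = "character", assay = "character", ranges = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@tfId) != 1L || !nzchar(object@tfId))
    msg <- c(msg, "tfId must be a non-empty scalar")
  if (!object@assay %in% c("chip", "dap", "pwm"))
    msg <- c(msg, "assay must be one of chip, dap, pwm")
  if (length(object@ranges) > 1L &&
      S4Vectors::isSorted(GenomicRanges::sort(object@ranges,
                                              ignore.strand = TRUE)) &&
      !identical(order(as.character(seqnames(object@ranges)),
                       GenomicRanges::start(object@ranges)),
                 seq_along(object@ranges)))
    msg <- c(msg, "peaks must be sorted")
  if (length(msg)) msg else TRUE
})

#' @param tfId TF/experiment identifier.
#' @param assay `"chip"`, `"dap"` or `"pwm"`.
#' @param ranges GRanges of peak intervals.
#' @rdname PeakSet-class
#' @export
PeakSet <- function(tfId, assay, ranges) {
  ranges <- GenomicRanges::sort(ranges, ignore.strand = TRUE)
  new("PeakSet", tfId = tfId, assay = assay, ranges = ranges)
}
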