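#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname chromTF-accessors
setMethod("states", "StateSegmentation", function(x) x@states)
#' @rdname chromTF-accessors
setMethod("states", "EmissionMatrix", function(x) rownames(x@p))
#' @rdname chromTF-accessors
setMethod("chromSizes", "StateSegmentation", function(x) x@chromSizes)
#' @rdname chromTF-accessors
setMethod("binSize", "StateSegmentation", function(x) x@binSize)
#' @rdname chromTF-accessors
setMethod("marks", "EmissionMatrix", function(x) colnames(x@p))
#' @rdname chromTF-accessors
setMethod("emissions", "EmissionMatrix", function(x) x@p)

#' @rdname chromTF-accessors
setMethod("geneIds", "GeneModelSet", function(x) x@ranges$gene_id)

#' @rdname chromTF-accessors
setMethod("tss", "GeneModelSet", function(x) {
  gr <- x@ranges
  ifelse(as.character(GenomicRanges::strand(gr)) == "+",
         GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
})

#' @rdname chromTF-accessors
setMethod("tts", "GeneModelSet", function(x) {
  gr <- x@ranges
  ifelse(as.character(GenomicRanges::strand(gr)) == "+",
         GenomicRanges::end(gr), GenomicRanges::start(gr) - 1L)
})

#' @rdname chromTF-accessors
setMethod("featureClass", "GeneModelSet", function(x) x@ranges$feature_class)

#' @rdname chromTF-accessors
setMethod("tfId", "PeakSet", function(x) x@tfId)
#' @rdname chromTF-accessors
setMethod("assayType", "PeakSet", function(x) x@assay)

#' @importMethodsFrom GenomicRanges granges
#' @rdname chromTF-accessors
#' @param use.names,use.mcols,... as for the GRanges method; `use.mcols =
#'   TRUE` keeps the metadata columns (`state`, `gene_id`, ...).
setMethod("granges", "StateSegmentation",
  function(x, use.names = TRUE, use.mcols = TRUE, ...) {
    if (use.mcols) x@ranges else granges(x@ranges)
  })
#' @rdname chromTF-accessors
setMethod("granges", "GeneModelSet",
  function(x, use.names = TRUE, use.mcols = TRUE, ...) {
    if (use.mcols) x@ranges else granges(x@ranges)
  })
#' @rdname chromTF-accessors
setMethod("granges", "PeakSet",
  function(x, use.names = TRUE, use.mcols = TRUE, ...) {
    if (use.mcols) x@ranges else granges(x@ranges)
  })

setMethod("length", "GeneModelSet", function(x) length(x@ranges))
setMethod("length", "PeakSet", function(x) length(x@ranges))
setMethod("length", "StateSegmentation", function(x) length(x@ranges))

setMethod("show", "StateSegmentation", function(object) {
  cat("StateSegmentation:", length(object@ranges), "intervals,",
      length(object@states), "states,",
      length(object@chromSizes), "chromosomes,",
      "bin", object@binSize, "bp\n")
  cat("  states:", paste(object@states, collapse = " "), "\n")
  ua <- sum(GenomicRanges::width(object@ranges[object@ranges$state ==
                                                 UNASSIGNED]))
  if (ua > 0) cat("  unassigned bp:", ua, "\n")
})

setMethod("show", "EmissionMatrix", function(object) {
  cat("EmissionMatrix:", nrow(object@p), "states x",
      ncol(object@p), "marks\n")
})

setMethod("show", "GeneModelSet", function(object) {
  tab <- table(object@ranges$feature_class)
  cat("GeneModelSet:", length(object@ranges), "genes (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", object@tfId, "[", object@assay, "],",
      length(object@ranges), "peaks\n")
})

#' Peak centers on the 0-based scale
#'
#' The center of a peak `[start0, end0)` is `floor((start0 + end0) / 2)`, a
#' deterministic choice consistent with half-open arithmetic.  Returned as a
#' 0-based coordinate.
#'
#' @param x A [PeakSet] or GRanges.
#' @return Integer vector of 0-based center positions.
#' @export
peakCenters <- function(x) {
  gr <- if (is(x, "PeakSet")) x@ranges else x
  as.integer((GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2)
}

## Per-bin state lookup: list, one character vector per chromosome, element
## i = state of bin [ (i-1)*binSize, i*binSize ).  Intervals are bin-aligned
## by class validity, so each bin is homogeneous.
.binStates <- function(seg) {
  gr <- seg@ranges
  bs <- seg@binSize
  out <- vector("list", length(seg@chromSizes))
  names(out) <- names(seg@chromSizes)
  chr <- as.character(seqnames(gr))
  for (c in names(out)) {
    g <- gr[chr == c]
    nb <- as.integer(ceiling(seg@chromSizes[[c]] / bs))
    s0 <- GenomicRanges::start(g) - 1L
    w <- GenomicRanges::end(g) - s0
    nbins <- as.integer(ceiling(w / bs))
    out[[c]] <- rep(g$state, nbins)[seq_len(nb)]
  }
  out
}

## bp per state label over the whole genome (includes "unassigned" entry
## when present)
.stateBp <- function(seg) {
  gr <- seg@ranges
  tapply(GenomicRanges::width(gr), gr$state, sum)
}

## Genome fraction over assigned bp, ordered as states(seg); states absent
## from the map get 0.
.stateFractions <- function(seg) {
  bp <- .stateBp(seg)
  bp <- bp[setdiff(names(bp), UNASSIGNED)]
  tot <- sum(bp)
  f <- stats::setNames(numeric(length(seg@states)), seg@states)
  f[names(bp)] <- bp / tot
  f
}

## Anchor bin: the segmentation-grid bin containing the first transcribed
## base.  pos is the 0-based TSS/TTS coordinate (= interval start for '+',
## interval end for '-'); for '-' anchors the coordinate is an exclusive
## boundary, so the covered base is pos - 1.
.anchorBin <- function(pos, strand, binSize) {
  as.integer(ifelse(strand == "+", pos, pos - 1) %/% binSize)
}
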