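#' @include methods.R
NULL

#' Percent of the genome covered by each state
#'
#' `100 * bp(state) / total bp`, with the denominator taken over assigned
#' base pairs by default, so the percentages always sum to 100 even when
#' the input segmentation left bins uncalled.
#'
#' @param seg A [StateSegmentation].
#' @param denominator `"assigned"` (default) or `"genome"` to divide by the
#'   full chromosome lengths including unassigned bp.
#' @return Named numeric vector of percentages, ordered as `states(seg)`.
#' @export
genomeCoverage <- function(seg, denominator = c("assigned", "genome")) {
  denominator <- match.arg(denominator)
  if (length(seg@ranges) == 0L) stop("empty segmentation")
  bp <- .stateBp(seg)
  bp <- bp[setdiff(names(bp), UNASSIGNED)]
  tot <- if (denominator == "assigned") sum(bp) else sum(seg@chromSizes)
  out <- stats::setNames(numeric(length(seg@states)), seg@states)
  out[names(bp)] <- 100 * bp / tot
  out
}

## Disjoint genomic partition by feature class, priority
## protein_coding > TE > other; strand ignored.
.featurePartition <- function(genes) {
  gr <- granges(genes, use.mcols = TRUE)
  GenomicRanges::strand(gr) <- "*"
  fc <- gr$feature_class
  pc <- GenomicRanges::reduce(gr[fc == "protein_coding"])
  te <- GenomicRanges::setdiff(GenomicRanges::reduce(gr[fc == "TE"]), pc)
  ot <- GenomicRanges::setdiff(GenomicRanges::reduce(gr[fc == "other"]),
                               GenomicRanges::union(pc, te))
  list(protein_coding = pc, TE = te, other = ot)
}

#' Feature composition of each chromatin state
#'
#' Base-pair overlap of every state with protein-coding genes, transposable
#' elements, other annotated features, and intergenic space, as
#' proportions summing to 1 per state.  Overlapping annotations are
#' resolved by the priority protein_coding > TE > other.
#'
#' @param seg A [StateSegmentation].
#' @param genes A [GeneModelSet] on the same chromosome namespace.
#' @return Matrix states x `{protein_coding, TE, other, intergenic}`.
#' @export
featureComposition <- function(seg, genes) {
  part <- .featurePartition(genes)
  st <- seg@states
  out <- matrix(0, length(st), 4,
                dimnames = list(st, c("protein_coding", "TE", "other",
                                      "intergenic")))
  gr <- seg@ranges
  for (s in st) {
    sgr <- gr[gr$state == s]
    tot <- sum(GenomicRanges::width(sgr))
    if (tot == 0) next
    covered <- 0
    for (cl in names(part)) {
      bp <- sum(GenomicRanges::width(GenomicRanges::intersect(sgr, part[[cl]],
                                                              ignore.strand = TRUE)))
      out[s, cl] <- bp / tot
      covered <- covered + bp
    }
    out[s, "intergenic"] <- (tot - covered) / tot
  }
  out
}

## Normalise anchors to a data.frame(chrom, pos, strand); pos 0-based.
.anchorFrame <- function(anchors, anchor = c("tss", "tts")) {
  anchor <- match.arg(anchor)
  if (is(anchors, "GeneModelSet")) {
    gr <- anchors@ranges
    pos <- if (anchor == "tss") tss(anchors) else tts(anchors)
    data.frame(chrom = as.character(seqnames(gr)), pos = pos,
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(anchors)
    stopifnot(all(c("chrom", "pos", "strand") %in% names(df)))
    df[c("chrom", "pos", "strand")]
  }
}

#' Neighbourhood enrichment of states around TSS/TTS anchors
#'
#' For each state `s` and signed bin offset `k` in `-L..L`,
#' `enrichment(s, k)` is the fraction of anchors whose bin at offset `k`
#' carries state `s`, divided by the genome fraction of `s` (over assigned
#' bp).  Offsets are counted on the segmentation's own bin grid; offset 0
#' is the bin containing the first transcribed base, and offsets are
#' mirrored for `-` strand anchors so positive offsets always point into
#' the gene.  Anchors whose offset bin falls outside the chromosome, or on
#' an unassigned bin, are excluded from that offset's denominator.  States
#' with zero genome fraction get `NA`, never `Inf`.
#'
#' @param seg A [StateSegmentation].
#' @param anchors A [GeneModelSet], or a data.frame with columns `chrom`,
#'   `pos` (0-based), `strand`.
#' @param L Half-window in bins (default 10, i.e. +-2 kb at 200 bp bins).
#' @param anchor `"tss"` (default) or `"tts"` when `anchors` is a
#'   [GeneModelSet].
#' @return A `NeighbourhoodMatrix` (list with `enrichment` and `fraction`
#'   matrices states x offsets, per-offset anchor counts `n`, and the
#'   state genome fractions used).
#' @export
neighbourhoodEnrichment <- function(seg, anchors, L = 10,
                                    anchor = c("tss", "tts")) {
  stopifnot(L >= 1)
  af <- .anchorFrame(anchors, anchor)
  bs <- .binStates(seg)
  gf <- .stateFractions(seg)
  offs <- seq(-L, L)
  st <- seg@states
  frac <- matrix(0, length(st), length(offs),
                 dimnames = list(st, as.character(offs)))
  n <- stats::setNames(integer(length(offs)), as.character(offs))
  b0 <- .anchorBin(af$pos, af$strand, seg@binSize)
  dir <- ifelse(af$strand == "+", 1L, -1L)
  nbins <- vapply(bs, length, 1L)
  nb <- nbins[af$chrom]
  for (j in seq_along(offs)) {
    k <- offs[j]
    bin <- b0 + k * dir
    valid <- bin >= 0L & bin < nb
    labs <- rep(NA_character_, nrow(af))
    if (any(valid)) {
      idx <- which(valid)
      labs[idx] <- mapply(function(c, b) bs[[c]][b + 1L],
                          af$chrom[idx], bin[idx])
    }
    keep <- !is.na(labs) & labs != UNASSIGNED
    n[j] <- sum(keep)
    if (n[j] > 0) {
      tab <- table(factor(labs[keep], levels = st))
      frac[, j] <- as.numeric(tab) / n[j]
    }
  }
  enr <- frac / ifelse(gf > 0, gf, NA)
  structure(list(enrichment = enr, fraction = frac, n = n,
                 genomeFraction = gf,
                 anchor = match.arg(anchor), L = L,
                 excluded = nrow(af) - n),
            class = "NeighbourhoodMatrix")
}

#' @export
print.NeighbourhoodMatrix <- function(x, ...) {
  cat("NeighbourhoodMatrix:", nrow(x$enrichment), "states x",
      ncol(x$enrichment), "offsets (anchor:", x$anchor, ", L =", x$L, ")\n")
  invisible(x)
}

#' Per-window counts of state bins along chromosomes
#'
#' Tiles every chromosome with fixed-width windows (50 kb by default, as
#' used for chromosomal state histograms) and counts, per state, how many
#' segmentation bins start in each window.
#'
#' @param seg A [StateSegmentation].
#' @param statesSubset States to count (default all); an empty subset
#'   yields a zero-column matrix.
#' @param binwidth Window width in bp.
#' @return Matrix windows x states; row names are `chrom:start` with
#'   0-based window starts.
#' @export
chromosomalDistribution <- function(seg, statesSubset = states(seg),
                                    binwidth = 50000) {
  stopifnot(binwidth > 0)
  bs <- .binStates(seg)
  rows <- character()
  counts <- list()
  for (c in names(bs)) {
    nwin <- as.integer(ceiling(seg@chromSizes[[c]] / binwidth))
    starts0 <- (seq_len(nwin) - 1L) * binwidth
    binStart0 <- (seq_along(bs[[c]]) - 1L) * seg@binSize
    win <- binStart0 %/% binwidth
    rows <- c(rows, paste0(c, ":", format(starts0, scientific = FALSE,
                                          trim = TRUE)))
    m <- matrix(0L, nwin, length(statesSubset),
                dimnames = list(NULL, statesSubset))
    for (s in statesSubset) {
      t <- table(factor(win[bs[[c]] == s], levels = 0:(nwin - 1L)))
      m[, s] <- as.integer(t)
    }
    counts[[c]] <- m
  }
  out <- do.call(rbind, counts)
  rownames(out) <- rows
  out
}

## Inverse-CDF (type 1) quantile of values x with positive integer-ish
## weights w; equals stats::quantile(rep(x, w), type = 1).
.weightedQuantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- sum(w)
  cw <- cumsum(w)
  vapply(p, function(pp) {
    if (pp <= 0) return(x[1])
    x[which(cw >= ceiling(n * pp))[1]]
  }, numeric(1))
}

#' Aggregate a signal track by chromatin state
#'
#' Overlaps a bedGraph-style signal with the state map and summarises the
#' bp-weighted value distribution per state (the box-plot statistic set).
#' State bp not covered by the signal counts as value 0; signal on unknown
#' chromosomes is skipped with a warning; overlapping signal intervals are
#' an error.
#'
#' @param seg A [StateSegmentation].
#' @param signal GRanges with a numeric `score` column (e.g. from
#'   [readBedGraph()]).
#' @return data.frame: state, n_bp, mean, q25, median, q75, min, max.
#' @export
aggregateSignalByState <- function(seg, signal) {
  unknown <- setdiff(unique(as.character(seqnames(signal))),
                     names(seg@chromSizes))
  if (length(unknown)) {
    warning("skipping signal on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    signal <- signal[!as.character(seqnames(signal)) %in% unknown]
  }
  red <- GenomicRanges::reduce(granges(signal))
  if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(signal)))
    stop("signal intervals overlap within a chromosome")
  gr <- seg@ranges
  rows <- lapply(seg@states, function(s) {
    sgr <- gr[gr$state == s]
    totBp <- sum(GenomicRanges::width(sgr))
    hits <- GenomicRanges::findOverlaps(sgr, signal, ignore.strand = TRUE)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      sgr[S4Vectors::queryHits(hits)], signal[S4Vectors::subjectHits(hits)]))
    v <- signal$score[S4Vectors::subjectHits(hits)]
    pad <- totBp - sum(w)
    if (pad > 0) { v <- c(v, 0); w <- c(w, pad) }
    if (length(v) == 0L) { v <- 0; w <- 0 }
    q <- .weightedQuantile(v, w, c(0.25, 0.5, 0.75))
    data.frame(state = s, n_bp = totBp,
               mean = sum(v * w) / sum(w),
               q25 = q[1], median = q[2], q75 = q[3],
               min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}
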