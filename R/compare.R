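#' @include states.R
NULL

## Overlap bp for every (stateA, stateB) label pair; unassigned excluded.
.overlapBp <- function(segA, segB) {
  grA <- segA@ranges[segA@ranges$state != UNASSIGNED]
  grB <- segB@ranges[segB@ranges$state != UNASSIGNED]
  hits <- GenomicRanges::findOverlaps(grA, grB, ignore.strand = TRUE)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    grA[S4Vectors::queryHits(hits)], grB[S4Vectors::subjectHits(hits)]))
  m <- matrix(0, length(segA@states), length(segB@states),
              dimnames = list(segA@states, segB@states))
  bp <- tapply(w, list(factor(grA$state[S4Vectors::queryHits(hits)],
                              levels = segA@states),
                       factor(grB$state[S4Vectors::subjectHits(hits)],
                              levels = segB@states)),
               sum, default = 0)
  m[rownames(bp), colnames(bp)] <- bp
  m
}

#' Transition matrix between two state maps
#'
#' Base pairs of co-occurrence between every state of model A and every
#' state of model B over the shared genome; unassigned bins of either map
#' are excluded, so the matrix total equals the bp assigned in both.
#'
#' @param segA,segB Two [StateSegmentation]s over the same chromosomes.
#' @return Matrix statesA x statesB of overlapping bp.
#' @export
transitionMatrix <- function(segA, segB) {
  if (length(intersect(names(segA@chromSizes), names(segB@chromSizes))) == 0L)
    stop("segmentations share no chromosomes")
  .overlapBp(segA, segB)
}

#' Per-state Jaccard similarity between two state maps
#'
#' `J(a, b) = bp(a intersect b) / bp(a union b)`, computed at base-pair
#' resolution.  States with zero assigned bp yield a zero row/column with a
#' warning.
#'
#' @inheritParams transitionMatrix
#' @return Matrix statesA x statesB of Jaccard indices in `[0, 1]`.
#' @export
stateJaccard <- function(segA, segB) {
  inter <- transitionMatrix(segA, segB)
  bpA <- .stateBp(segA)[rownames(inter)]
  bpB <- .stateBp(segB)[colnames(inter)]
  bpA[is.na(bpA)] <- 0
  bpB[is.na(bpB)] <- 0
  if (any(bpA == 0) || any(bpB == 0))
    warning("state(s) with zero bp: ",
            paste(c(rownames(inter)[bpA == 0], colnames(inter)[bpB == 0]),
                  collapse = ", "))
  uni <- outer(bpA, bpB, `+`) - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Best-match Jaccard after in-silico mark removal
#'
#' For each reduced model (a segmentation re-learned without some mark set)
#' and each state of the full model, finds the reduced state with maximal
#' Jaccard overlap.  If a domain assignment is supplied the best-match
#' similarities are also averaged per chromatin domain, quantifying which
#' domains a mark set is most needed to define.
#'
#' @param fullSeg The full-model [StateSegmentation].
#' @param reducedSegs Named list of reduced-model segmentations
#'   (name = removed mark set).
#' @param domains Optional data.frame from [classifyDomains()] for the full
#'   model.
#' @return list with `perState` (removal, full_state, best_match, jaccard)
#'   and `byDomain` (removal, domain, mean_jaccard; `NULL` without
#'   `domains`).
#' @export
markRemovalExperiment <- function(fullSeg, reducedSegs, domains = NULL) {
  perState <- do.call(rbind, lapply(names(reducedSegs), function(nm) {
    J <- stateJaccard(fullSeg, reducedSegs[[nm]])
    data.frame(removal = nm, full_state = rownames(J),
               best_match = colnames(J)[apply(J, 1, which.max)],
               jaccard = apply(J, 1, max), row.names = NULL)
  }))
  byDomain <- NULL
  if (!is.null(domains)) {
    dom <- stats::setNames(domains$domain, domains$state)
    perState$domain <- dom[perState$full_state]
    agg <- stats::aggregate(jaccard ~ removal + domain, perState, mean)
    names(agg)[3] <- "mean_jaccard"
    byDomain <- agg
  }
  list(perState = perState, byDomain = byDomain)
}

#' Cross-species clustering of emission matrices
#'
#' Merges two emission matrices on their shared marks (after applying
#' `markMap`, which renames marks of B into A's namespace — e.g. treating
#' one species' H2A.W and the other's H2A.M.2 as the same variant) and
#' hierarchically clusters the pooled states.
#'
#' @param emissA,emissB Two [EmissionMatrix] objects.
#' @param markMap Optional named character vector: names are marks of B,
#'   values the corresponding marks of A.  Unmapped, non-shared marks are
#'   dropped with a warning.
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param prefixes Length-2 labels prepended to the state names of A and B.
#' @return list: `matrix` (pooled states x common marks), `hclust`, and
#'   `merges` (a language-neutral merge table: `i`, `j`, `height`, with
#'   negative indices denoting leaves as in [stats::hclust()]).
#' @export
emissionClustering <- function(emissA, emissB, markMap = NULL,
                               metric = "euclidean", linkage = "average",
                               prefixes = c("A.", "B.")) {
  a <- emissA@p
  b <- emissB@p
  if (!is.null(markMap)) {
    hit <- colnames(b) %in% names(markMap)
    colnames(b)[hit] <- unname(markMap[colnames(b)[hit]])
  }
  common <- intersect(colnames(a), colnames(b))
  dropped <- c(setdiff(colnames(a), common), setdiff(colnames(b), common))
  if (length(common) < 2L)
    stop("fewer than 2 common marks after mapping")
  if (length(dropped))
    warning("dropping unmapped mark(s): ", paste(unique(dropped),
                                                 collapse = ", "))
  m <- rbind(a[, common, drop = FALSE], b[, common, drop = FALSE])
  rownames(m) <- c(paste0(prefixes[1], rownames(a)),
                   paste0(prefixes[2], rownames(b)))
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  list(matrix = m, hclust = hc,
       merges = data.frame(i = hc$merge[, 1], j = hc$merge[, 2],
                           height = hc$height))
}

#' Update gene TSS/TTS from experimentally determined anchors
#'
#' Assigns each stranded anchor point (e.g. a CAGE or 5'/3' tag peak) to
#' the nearest gene TSS (or TTS) on the same strand within `maxDistance`
#' bp; equidistant candidates go to the gene with the lexicographically
#' smaller id.  Genes receiving several anchors keep the nearest one.
#' Matched genes get updated coordinates; the per-gene shift is
#' `new - old` with the sign flipped on `-` strand genes, so positive
#' shifts always point downstream.
#'
#' @param genes A [GeneModelSet].
#' @param anchors Stranded GRanges of point features (width 1; the 0-based
#'   position used is `start - 1`).
#' @param type `"tss"` (default) or `"tts"`.
#' @param maxDistance Maximum anchor-to-gene distance in bp (default 500).
#' @return list: `genes` (updated [GeneModelSet]), `shifts` (data.frame
#'   `gene_id`, `shift`), `unmatched` (number of unassigned anchors).
#' @export
updateCoordinates <- function(genes, anchors, type = c("tss", "tts"),
                              maxDistance = 500) {
  type <- match.arg(type)
  gr <- genes@ranges
  t0 <- if (type == "tss") tss(genes) else tts(genes)
  gchr <- as.character(seqnames(gr))
  gstr <- as.character(GenomicRanges::strand(gr))
  apos <- GenomicRanges::start(anchors) - 1L
  achr <- as.character(seqnames(anchors))
  astr <- as.character(GenomicRanges::strand(anchors))
  assignGene <- rep(NA_integer_, length(anchors))
  assignDist <- rep(NA_real_, length(anchors))
  for (i in seq_along(anchors)) {
    cand <- which(gchr == achr[i] & gstr == astr[i])
    if (!length(cand)) next
    d <- abs(t0[cand] - apos[i])
    ok <- d <= maxDistance
    if (!any(ok)) next
    cand <- cand[ok]; d <- d[ok]
    best <- cand[order(d, gr$gene_id[cand])][1]
    assignGene[i] <- best
    assignDist[i] <- min(d)
  }
  unmatched <- sum(is.na(assignGene))
  hitIdx <- which(!is.na(assignGene))
  newPos <- rep(NA_real_, length(gr))
  for (g in unique(assignGene[hitIdx])) {
    mine <- hitIdx[assignGene[hitIdx] == g]
    newPos[g] <- apos[mine[order(assignDist[mine], apos[mine])][1]]
  }
  upd <- which(!is.na(newPos))
  shift <- numeric(0)
  keptIds <- character(0)
  out <- gr
  for (g in upd) {
    np <- newPos[g]
    s0 <- GenomicRanges::start(gr)[g] - 1L
    e0 <- GenomicRanges::end(gr)[g]
    movingStart <- (type == "tss") == (gstr[g] == "+")
    if (movingStart) { if (np >= e0) next } else if (np <= s0) next
    old <- t0[g]
    if (movingStart)
      GenomicRanges::start(out)[g] <- np + 1L
    else
      GenomicRanges::end(out)[g] <- np
    sh <- (np - old) * if (gstr[g] == "+") 1 else -1
    shift <- c(shift, sh)
    keptIds <- c(keptIds, gr$gene_id[g])
  }
  list(genes = GeneModelSet(out),
       shifts = data.frame(gene_id = keptIds, shift = shift),
       unmatched = unmatched)
}

#' Jaccard similarity between two coordinate annotations
#'
#' Fraction of genes whose coordinates agree within a tolerance:
#' `|{genes present in both with |difference| <= tolerance}| /
#' |{genes with a coordinate in either set}|`.
#'
#' @param coordsA,coordsB Named numeric vectors gene -> coordinate (bp).
#' @param toleranceBp Agreement tolerance in bp (default 0).
#' @return Similarity in `[0, 1]`.
#' @export
coordinateSetJaccard <- function(coordsA, coordsB, toleranceBp = 0) {
  coordsA <- coordsA[!is.na(coordsA)]
  coordsB <- coordsB[!is.na(coordsB)]
  uni <- union(names(coordsA), names(coordsB))
  if (!length(uni)) return(NA_real_)
  both <- intersect(names(coordsA), names(coordsB))
  agree <- sum(abs(coordsA[both] - coordsB[both]) <= toleranceBp)
  agree / length(uni)
}
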