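#' @include methods.R
NULL

#' Assign each peak the chromatin state of its center
#'
#' Only the center of the peak is used: the state of the segmentation bin
#' containing `floor((start0 + end0) / 2)`.  Peaks whose center falls on an
#' unassigned bin are labelled `"unassigned"`.
#'
#' @param peaks A [PeakSet] (or GRanges).
#' @param seg A [StateSegmentation].
#' @return Character vector of state labels, one per peak.
#' @export
assignPeakStates <- function(peaks, seg) {
  gr <- if (is(peaks, "PeakSet")) peaks@ranges else peaks
  if (length(gr) == 0L) return(character(0))
  centers <- peakCenters(gr)
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(seg@chromSizes))
  if (length(unknown))
    stop("peaks on chromosome(s) absent from segmentation: ",
         paste(unknown, collapse = ", "))
  bs <- .binStates(seg)
  bin <- centers %/% seg@binSize
  vapply(seq_along(gr), function(i) bs[[chr[i]]][bin[i] + 1L], character(1))
}

#' TF occupancy enrichment across chromatin states
#'
#' Base-pair level over/under-representation of a TF's peaks in each state
#' `s`: `(a_s / b) / (c_s / d)` where `a_s` is the peak bp in `s`, `b` the
#' total peak bp on assigned genome, `c_s` the bp of `s` and `d` the total
#' assigned bp.  Peaks are merged before counting so overlapping peaks do
#' not double-count bases.  States with `c_s = 0` are reported with `NA`
#' enrichment.
#'
#' @param peaks A [PeakSet].
#' @param seg A [StateSegmentation].
#' @return data.frame: tf_id, state, a (peak bp in state), b, c (state
#'   bp), d, enrichment.
#' @export
occupancyEnrichment <- function(peaks, seg) {
  pk <- GenomicRanges::reduce(granges(peaks, use.mcols = FALSE),
                              ignore.strand = TRUE)
  if (length(pk) == 0L || sum(GenomicRanges::width(pk)) == 0)
    stop("peak set '", tfId(peaks), "' has zero total bp")
  gr <- seg@ranges[seg@ranges$state != UNASSIGNED]
  hits <- GenomicRanges::findOverlaps(gr, pk, ignore.strand = TRUE)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    gr[S4Vectors::queryHits(hits)], pk[S4Vectors::subjectHits(hits)]))
  a <- tapply(w, factor(gr$state[S4Vectors::queryHits(hits)],
                        levels = seg@states), sum, default = 0)
  a <- stats::setNames(as.numeric(a), seg@states)
  b <- sum(a)
  if (b == 0) stop("peak set '", tfId(peaks),
                   "' does not overlap the assigned genome")
  cs <- .stateBp(seg)
  cs <- stats::setNames(as.numeric(cs[seg@states]), seg@states)
  cs[is.na(cs)] <- 0
  d <- sum(cs)
  enr <- ifelse(cs > 0, (a / b) / (cs / d), NA_real_)
  data.frame(tf_id = tfId(peaks), state = seg@states, a = a, b = b,
             c = cs, d = d, enrichment = enr, row.names = NULL)
}

## Nearest TSS lookup: for 0-based positions on one chromosome, return the
## index (into the full gene set) of the nearest TSS; ties go to the
## lexicographically smaller gene id.
.nearestTss <- function(pos, chr, genes) {
  t0 <- tss(genes)
  gchr <- as.character(seqnames(genes@ranges))
  ids <- genes@ranges$gene_id
  out <- rep(NA_integer_, length(pos))
  dist <- rep(NA_real_, length(pos))
  for (c in unique(chr)) {
    gi <- which(gchr == c)
    if (!length(gi)) next
    o <- gi[order(t0[gi], ids[gi])]
    ts <- t0[o]
    pi <- which(chr == c)
    lo <- findInterval(pos[pi], ts)
    for (jj in seq_along(pi)) {
      cand <- o[unique(pmin(pmax(c(lo[jj], lo[jj] + 1L), 1L), length(o)))]
      d <- abs(t0[cand] - pos[pi[jj]])
      ## widen to catch exact ties among equal-TSS genes
      best <- cand[order(d, ids[cand])][1]
      tied <- gi[abs(t0[gi] - pos[pi[jj]]) == min(d)]
      best <- tied[order(ids[tied])][1]
      out[pi[jj]] <- best
      dist[pi[jj]] <- min(d)
    }
  }
  list(index = out, distance = dist)
}

#' Annotate TF peaks with target genes, per chromatin state
#'
#' Assigns every peak to a gene by an ordered rule cascade on the peak
#' center: (1) center inside a promoter window around some TSS (default
#' 1000 bp upstream to 100 bp downstream, strand-aware) -> that gene
#' (nearest TSS if several qualify); (2) center inside a gene body -> that
#' gene; (3) otherwise the nearest TSS within `maxDistance` bp, else
#' unassigned.  The per-state target set is the union of the genes of the
#' peaks carrying that state.
#'
#' @param peaks A [PeakSet].
#' @param genes A [GeneModelSet].
#' @param seg A [StateSegmentation] (for per-peak states).
#' @param promoterWindow Length-2 numeric `c(upstream, downstream)` bp
#'   around the TSS (default `c(1000, 100)`).
#' @param maxDistance Distal assignment cutoff in bp (default 10000).
#' @return list: `assignments` (data.frame peak, center, state, gene_id,
#'   rule) and `targetsByState` (named list state -> character vector of
#'   gene ids).
#' @export
annotateTargets <- function(peaks, genes, seg,
                            promoterWindow = c(1000, 100),
                            maxDistance = 10000) {
  st <- assignPeakStates(peaks, seg)
  gr <- peaks@ranges
  centers <- peakCenters(gr)
  chr <- as.character(seqnames(gr))
  t0 <- tss(genes)
  gchr <- as.character(seqnames(genes@ranges))
  gstr <- as.character(GenomicRanges::strand(genes@ranges))
  gs0 <- GenomicRanges::start(genes@ranges) - 1L
  ge0 <- GenomicRanges::end(genes@ranges)
  ids <- genes@ranges$gene_id
  up <- promoterWindow[1]; down <- promoterWindow[2]
  promS <- ifelse(gstr == "+", t0 - up, t0 - down)
  promE <- ifelse(gstr == "+", t0 + down, t0 + up)
  gene <- rep(NA_character_, length(gr))
  rule <- rep("unassigned", length(gr))
  near <- .nearestTss(centers, chr, genes)
  for (i in seq_along(gr)) {
    onChr <- gchr == chr[i]
    inProm <- onChr & centers[i] >= promS & centers[i] < promE
    if (any(inProm)) {
      cand <- which(inProm)
      d <- abs(t0[cand] - centers[i])
      gene[i] <- ids[cand[order(d, ids[cand])][1]]
      rule[i] <- "promoter"
      next
    }
    inBody <- onChr & centers[i] >= gs0 & centers[i] < ge0
    if (any(inBody)) {
      cand <- which(inBody)
      d <- abs(t0[cand] - centers[i])
      gene[i] <- ids[cand[order(d, ids[cand])][1]]
      rule[i] <- "gene_body"
      next
    }
    if (!is.na(near$index[i]) && near$distance[i] <= maxDistance) {
      gene[i] <- ids[near$index[i]]
      rule[i] <- "nearest_tss"
    }
  }
  assignments <- data.frame(peak = seq_along(gr), center = centers,
                            state = st, gene_id = gene, rule = rule)
  keep <- !is.na(gene)
  targets <- split(gene[keep], factor(st[keep], levels = seg@states))
  targets <- lapply(targets, function(g) sort(unique(g)))
  list(assignments = assignments, targetsByState = targets)
}

#' Positively and negatively co-expressed genes of a TF
#'
#' ATTED-style rank filter: the positive set holds genes with score
#' strictly below `positiveMax` (2000 by default), the negative set genes
#' with score strictly above `max(score) - negativeWindow` (1000 by
#' default), the maximum taken over that TF's own entries.
#'
#' @param coexpr data.frame `tf_id`, `gene_id`, `score` (lower = more
#'   positively co-expressed).
#' @param tf TF identifier; must be present in the table.
#' @param positiveMax Positive-set threshold (default 2000).
#' @param negativeWindow Width of the negative tail (default 1000).
#' @return list: `positive`, `negative` (character vectors of gene ids).
#' @export
coexpressionFilter <- function(coexpr, tf, positiveMax = 2000,
                               negativeWindow = 1000) {
  d <- coexpr[coexpr$tf_id == tf, ]
  if (nrow(d) == 0L) stop("TF '", tf, "' absent from co-expression table")
  list(positive = sort(d$gene_id[d$score < positiveMax]),
       negative = sort(d$gene_id[d$score > max(d$score) - negativeWindow]))
}

## One-sided (greater) exact hypergeometric p for the 2x2 table with
## margins (m targets, q co-expressed, N genes) and overlap k.
.hyperP <- function(k, m, q, N) {
  stats::phyper(k - 1, q, N - q, m, lower.tail = FALSE)
}

.sampleOR <- function(k, m, q, N) {
  a <- k; b <- m - k; c <- q - k; d <- N - m - q + k
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' TF activity score per chromatin state
#'
#' For each state, tests whether the TF's target genes in that state are
#' enriched for the TF's co-expressed genes, against the whole-genome gene
#' universe: a one-sided (greater) Fisher exact test on the 2x2 table with
#' cells `(k, m - k; q - k, N - m - q + k)`, where `k` is the overlap,
#' `m` the targets in the state, `q` the co-expressed genes and `N` the
#' universe size.  The activity score is
#' `-log10(p) + log2(odds ratio + 1)`, with the sample odds ratio given a
#' Haldane 0.5 correction when any cell is zero; states without targets
#' score 0 (`p = 1`, `OR = 0`).  Normalized scores divide by the TF's
#' maximum raw score.
#'
#' @param targetsByState Named list state -> target gene ids (from
#'   [annotateTargets()]).
#' @param coexpressed Character vector of the TF's co-expressed genes
#'   (positive and negative sets pooled).
#' @param universe Character vector of all gene ids (defines `N`).
#' @param tf TF identifier carried into the output.
#' @param tableConvention `"derived"` (default; margins-derived 2x2) or
#'   `"literal"` to also report the literal printed count layout
#'   `(k, m; q, N)` — statistically incoherent but kept for comparison.
#' @return data.frame: tf_id, state, k, m, q, N, p_value, odds_ratio,
#'   raw_score, normalized_score.
#' @export
activityScore <- function(targetsByState, coexpressed, universe, tf = "TF",
                          tableConvention = c("derived", "literal")) {
  tableConvention <- match.arg(tableConvention)
  N <- length(unique(universe))
  coexpressed <- intersect(unique(coexpressed), universe)
  q <- length(coexpressed)
  rows <- lapply(names(targetsByState), function(s) {
    tg <- intersect(unique(targetsByState[[s]]), universe)
    m <- length(tg)
    k <- length(intersect(tg, coexpressed))
    if (m == 0L) {
      p <- 1; or <- 0
    } else if (tableConvention == "derived") {
      p <- .hyperP(k, m, q, N)
      or <- .sampleOR(k, m, q, N)
    } else {
      tab <- matrix(c(k, q, m, N), 2)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      or <- .sampleOR(k, m, q, N)
    }
    raw <- -log10(p) + log2(or + 1)
    data.frame(tf_id = tf, state = s, k = k, m = m, q = q, N = N,
               p_value = p, odds_ratio = or, raw_score = raw)
  })
  out <- do.call(rbind, rows)
  mx <- max(out$raw_score)
  out$normalized_score <- if (mx > 0) out$raw_score / mx else 0
  out
}

#' Build the TF-by-state activity score matrix
#'
#' Stacks per-TF activity results, drops TFs whose maximum raw score is
#' strictly below `minMaxScore` (8 by default, the low-confidence filter),
#' and normalizes each remaining row by its own maximum so every retained
#' TF peaks at 1.
#'
#' @param results data.frame of stacked [activityScore()] outputs, or a
#'   list of them.
#' @param minMaxScore Retention threshold on the per-TF max raw score.
#' @return list: `matrix` (retained TFs x states, normalized), `raw`
#'   (same shape, unnormalized), `dropped` (data.frame tf_id, max_score).
#' @export
buildScoreMatrix <- function(results, minMaxScore = 8) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  tfs <- unique(results$tf_id)
  st <- unique(results$state)
  raw <- matrix(0, length(tfs), length(st), dimnames = list(tfs, st))
  raw[cbind(match(results$tf_id, tfs), match(results$state, st))] <-
    results$raw_score
  mx <- apply(raw, 1, max)
  keep <- mx >= minMaxScore
  if (!any(keep)) stop("all TFs fall below the score threshold ", minMaxScore)
  dropped <- data.frame(tf_id = tfs[!keep], max_score = mx[!keep],
                        row.names = NULL)
  rawKeep <- raw[keep, , drop = FALSE]
  norm <- rawKeep / apply(rawKeep, 1, max)
  list(matrix = norm, raw = rawKeep, dropped = dropped)
}

#' Hierarchical clustering of TFs by chromatin-state preference
#'
#' Clusters the normalized TF-by-state score matrix (Euclidean distance and
#' complete linkage by default, both configurable) and cuts the tree at
#' `k` clusters.  Deterministic for fixed inputs.
#'
#' @param m Normalized score matrix from [buildScoreMatrix()].
#' @param k Number of clusters (>= 2).
#' @param metric Distance metric (default `"euclidean"`).
#' @param linkage Agglomeration method (default `"complete"`).
#' @return list: `matrix`, `hclust`, `merges`, `clusters` (named integer
#'   vector TF -> cluster in `1..k`), `k`.
#' @export
clusterTFs <- function(m, k, metric = "euclidean", linkage = "complete") {
  if (k < 2) stop("k must be >= 2")
  if (nrow(m) < k) stop("need at least k = ", k, " TFs")
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  cl <- stats::cutree(hc, k = k)
  list(matrix = m, hclust = hc,
       merges = data.frame(i = hc$merge[, 1], j = hc$merge[, 2],
                           height = hc$height),
       clusters = cl, k = k)
}

#' TF family enrichment across clusters
#'
#' One-sided (greater) Fisher exact test per (family, cluster) pair on the
#' overlap between family membership and cluster membership, with the same
#' margins-derived table convention as [activityScore()]; Benjamini-
#' Hochberg adjusted q-values are reported alongside raw p-values.  TFs
#' without a family label are pooled as `"unknown"`.
#'
#' @param clusterLabels Named vector TF -> cluster.
#' @param tfFamilies Named character vector TF -> family.
#' @return data.frame: family, cluster, k, cluster_size, family_size, N,
#'   p_value, q_value, odds_ratio.
#' @export
familyEnrichment <- function(clusterLabels, tfFamilies) {
  tfs <- names(clusterLabels)
  fam <- tfFamilies[tfs]
  fam[is.na(fam)] <- "unknown"
  N <- length(tfs)
  rows <- list()
  for (f in sort(unique(fam))) {
    for (cl in sort(unique(clusterLabels))) {
      inF <- fam == f
      inC <- clusterLabels == cl
      k <- sum(inF & inC)
      m <- sum(inC)
      q <- sum(inF)
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, cluster = cl, k = k, cluster_size = m,
        family_size = q, N = N,
        p_value = .hyperP(k, m, q, N),
        odds_ratio = .sampleOR(k, m, q, N))
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[c("family", "cluster", "k", "cluster_size", "family_size", "N",
        "p_value", "q_value", "odds_ratio")]
}

#' TSS-relative binding histograms per TF cluster
#'
#' Signed distance from each peak center to the nearest TSS, oriented by
#' that gene's strand (negative = upstream of the TSS), histogrammed per
#' cluster over `[-window, +window]`.
#'
#' @param peaksByCluster Named list cluster -> [PeakSet] or list of
#'   [PeakSet]s.
#' @param genes A [GeneModelSet].
#' @param window Half-window in bp (default 2000).
#' @param nbins Number of histogram bins (default 40).
#' @return Matrix clusters x bins of counts; column names are bin
#'   midpoints.
#' @export
tssBindingHistogram <- function(peaksByCluster, genes, window = 2000,
                                nbins = 40) {
  stopifnot(window > 0, nbins > 0)
  breaks <- seq(-window, window, length.out = nbins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  gstr <- as.character(GenomicRanges::strand(genes@ranges))
  out <- matrix(0L, length(peaksByCluster), nbins,
                dimnames = list(names(peaksByCluster),
                                format(mids, trim = TRUE)))
  for (cl in names(peaksByCluster)) {
    ps <- peaksByCluster[[cl]]
    if (is(ps, "PeakSet")) ps <- list(ps)
    grs <- unname(lapply(ps, granges, use.mcols = FALSE))
    gr <- do.call(c, grs)
    if (length(gr) == 0L) next
    centers <- peakCenters(gr)
    chr <- as.character(seqnames(gr))
    near <- .nearestTss(centers, chr, genes)
    ok <- !is.na(near$index)
    d <- (centers[ok] - tss(genes)[near$index[ok]]) *
      ifelse(gstr[near$index[ok]] == "-", -1, 1)
    d <- d[d >= -window & d <= window]
    idx <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L),
                nbins)
    t <- table(factor(idx, levels = seq_len(nbins)))
    out[cl, ] <- as.integer(t)
  }
  out
}
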