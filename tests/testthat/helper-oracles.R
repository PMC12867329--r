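## Independent brute-force oracles used to pin down the bp-overlap and
## exact-test operations.  Everything here works on explicit per-bp state
## vectors or closed-form enumeration, never on the package's interval
## arithmetic.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Build a StateSegmentation from a compact spec: list(chrom = c(stateA,
## stateB, ...)) with one label per bin.
segFromBins <- function(binsByChrom, binSize = 200) {
  rows <- lapply(names(binsByChrom), function(chr) {
    b <- binsByChrom[[chr]]
    r <- rle(b)
    e0 <- cumsum(r$lengths) * binSize
    s0 <- c(0, e0[-length(e0)])
    data.frame(chrom = chr, s0 = s0, e0 = e0, state = r$values)
  })
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$s0 + 1, df$e0), state = df$state)
  sizes <- sapply(binsByChrom, function(b) length(b) * binSize)
  StateSegmentation(gr, chromSizes = sizes, binSize = binSize)
}

## Random bin-aligned segmentation over 1-2 chromosomes.
randomSegmentation <- function(nStates = 4, maxBins = 120, binSize = 200,
                               nChroms = 2) {
  sts <- paste0("S", seq_len(nStates))
  bins <- lapply(seq_len(nChroms), function(i)
    sample(sts, sample(20:maxBins, 1), replace = TRUE))
  names(bins) <- paste0("chr", seq_len(nChroms))
  segFromBins(bins, binSize)
}

## Per-bp state vector per chromosome (character, length = chrom size).
perBpStates <- function(seg) {
  gr <- granges(seg, use.mcols = TRUE)
  out <- lapply(names(chromSizes(seg)), function(chr) {
    g <- gr[as.character(seqnames(gr)) == chr]
    g <- g[order(start(g))]
    rep(g$state, width(g))
  })
  names(out) <- names(chromSizes(seg))
  out
}

oracleCoverage <- function(seg) {
  v <- unlist(perBpStates(seg), use.names = FALSE)
  v <- v[v != unassignedLabel()]
  tab <- table(factor(v, levels = states(seg)))
  100 * as.numeric(tab) / length(v)
}

## Per-bp feature composition with priority protein_coding > TE > other.
oracleComposition <- function(seg, genes) {
  v <- perBpStates(seg)
  cls <- lapply(v, function(x) rep("intergenic", length(x)))
  gr <- granges(genes, use.mcols = TRUE)
  for (fc in c("other", "TE", "protein_coding")) {
    g <- gr[gr$feature_class == fc]
    for (i in seq_along(g)) {
      chr <- as.character(seqnames(g))[i]
      if (!chr %in% names(cls)) next
      idx <- start(g)[i]:min(end(g)[i], length(cls[[chr]]))
      cls[[chr]][idx] <- fc
    }
  }
  allState <- unlist(v, use.names = FALSE)
  allCls <- unlist(cls, use.names = FALSE)
  lev <- c("protein_coding", "TE", "other", "intergenic")
  t(sapply(states(seg), function(s) {
    tab <- table(factor(allCls[allState == s], levels = lev))
    as.numeric(tab) / sum(tab)
  }))
}

## bp tally of (stateA, stateB) label pairs at identical positions.
oracleTransition <- function(segA, segB) {
  vA <- perBpStates(segA)
  vB <- perBpStates(segB)
  common <- intersect(names(vA), names(vB))
  m <- matrix(0, length(states(segA)), length(states(segB)),
              dimnames = list(states(segA), states(segB)))
  for (chr in common) {
    n <- min(length(vA[[chr]]), length(vB[[chr]]))
    a <- vA[[chr]][seq_len(n)]
    b <- vB[[chr]][seq_len(n)]
    keep <- a != unassignedLabel() & b != unassignedLabel()
    t <- table(factor(a[keep], levels = states(segA)),
               factor(b[keep], levels = states(segB)))
    m <- m + as.matrix(t)
  }
  m
}

oracleJaccard <- function(segA, segB) {
  inter <- oracleTransition(segA, segB)
  vA <- unlist(perBpStates(segA), use.names = FALSE)
  vB <- unlist(perBpStates(segB), use.names = FALSE)
  bpA <- as.numeric(table(factor(vA, levels = states(segA))))
  bpB <- as.numeric(table(factor(vB, levels = states(segB))))
  uni <- outer(bpA, bpB, `+`) - inter
  ifelse(uni > 0, inter / uni, 0)
}

## Anchor-walk oracle for neighbourhood enrichment: per anchor, read the
## state at the first bp of the offset bin from the per-bp vector.
oracleNeighbourhood <- function(seg, anchorDf, L) {
  v <- perBpStates(seg)
  bs <- binSize(seg)
  sts <- states(seg)
  offs <- seq(-L, L)
  frac <- matrix(0, length(sts), length(offs),
                 dimnames = list(sts, as.character(offs)))
  n <- integer(length(offs))
  for (j in seq_along(offs)) {
    hits <- character(0)
    for (i in seq_len(nrow(anchorDf))) {
      pos <- anchorDf$pos[i]
      dir <- if (anchorDf$strand[i] == "+") 1 else -1
      b0 <- (if (dir == 1) pos else pos - 1) %/% bs
      b <- b0 + offs[j] * dir
      vec <- v[[anchorDf$chrom[i]]]
      nb <- ceiling(length(vec) / bs)
      if (b < 0 || b >= nb) next
      s <- vec[b * bs + 1]
      if (s == unassignedLabel()) next
      hits <- c(hits, s)
    }
    n[j] <- length(hits)
    if (n[j] > 0)
      frac[, j] <- as.numeric(table(factor(hits, levels = sts))) / n[j]
  }
  allBp <- unlist(v, use.names = FALSE)
  allBp <- allBp[allBp != unassignedLabel()]
  gf <- as.numeric(table(factor(allBp, levels = sts))) / length(allBp)
  list(fraction = frac, enrichment = frac / ifelse(gf > 0, gf, NA), n = n)
}

## bp-expanded oracle for signal aggregation.
oracleSignalStats <- function(seg, signal) {
  v <- perBpStates(seg)
  val <- lapply(v, function(x) numeric(length(x)))
  for (i in seq_along(signal)) {
    chr <- as.character(seqnames(signal))[i]
    if (!chr %in% names(val)) next
    idx <- start(signal)[i]:end(signal)[i]
    idx <- idx[idx <= length(val[[chr]])]
    val[[chr]][idx] <- signal$score[i]
  }
  allState <- unlist(v, use.names = FALSE)
  allVal <- unlist(val, use.names = FALSE)
  t(sapply(states(seg), function(s) {
    x <- sort(allVal[allState == s])
    n <- length(x)
    c(mean = mean(x),
      q25 = x[ceiling(0.25 * n)], median = x[ceiling(0.5 * n)],
      q75 = x[ceiling(0.75 * n)])
  }))
}

## Exhaustive one-sided (greater) Fisher p by closed-form hypergeometric
## pmf summed over all tables with the given margins.
enumFisherP <- function(k, m, q, N) {
  ks <- max(0, m + q - N):min(m, q)
  pmf <- choose(q, ks) * choose(N - q, m - ks) / choose(N, m)
  sum(pmf[ks >= k])
}

## Adjusted Rand index (contingency-table form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## Small gene set helper: data.frame -> GeneModelSet (coords 0-based
## half-open in s0/e0).
genesFromDf <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$s0 + 1, df$e0), strand = df$strand,
                gene_id = df$gene_id,
                feature_class = if (is.null(df$feature_class))
                  "protein_coding" else df$feature_class)
  GeneModelSet(gr)
}
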