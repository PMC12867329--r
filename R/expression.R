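#' @include io.R
NULL

#' Coefficient of variation of expression per gene
#'
#' CV = sample standard deviation / mean TPM across samples (the `n - 1`
#' estimator).  Genes with mean 0 get `NA` (they carry no variability
#' information and are excluded downstream); the number of such genes is
#' attached as attribute `n_undefined`.
#'
#' @param expr SummarizedExperiment (assay `tpm`) or genes-by-samples
#'   matrix; at least 2 samples.
#' @return Named numeric vector of CVs with `NA` for all-zero genes.
#' @export
computeCV <- function(expr) {
  m <- .tpmMatrix(expr)
  if (ncol(m) < 2L) stop("CV needs at least 2 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sd / mu, NA_real_)
  names(cv) <- rownames(m)
  structure(cv, n_undefined = sum(mu == 0))
}

#' Rank-based equal-size gene bins
#'
#' Orders genes by the given statistic (ties broken by gene id, so the
#' binning is stable) and splits them into `B` bins whose sizes differ by
#' at most one; bin 1 holds the lowest values.
#'
#' @param values Named numeric vector (gene -> statistic); `NA`s are
#'   dropped.
#' @param B Number of bins (default 20).
#' @return Named integer vector gene -> bin in `1..B`.
#' @export
binGenes <- function(values, B = 20) {
  if (B <= 0) stop("B must be positive")
  values <- values[!is.na(values)]
  if (length(values) < B)
    stop("need at least B = ", B, " genes with defined values")
  o <- order(values, names(values))
  bin <- as.integer(ceiling(seq_along(o) * B / length(o)))
  stats::setNames(bin[order(o)], names(values))
}

#' Promoter regions upstream of the TSS
#'
#' The 1,000 bp (by default) region upstream of each gene's TSS,
#' strand-aware: `[tss - length, tss)` for `+` genes, `[tss, tss + length)`
#' for `-` genes (0-based half-open), clipped at chromosome edges.
#'
#' @param genes A [GeneModelSet].
#' @param length Promoter length in bp (default 1000).
#' @param chromSizes Optional named sizes used for clipping on the right.
#' @return GRanges named by gene id, with a `clipped` column giving the bp
#'   lost to clipping.
#' @export
promoterRegions <- function(genes, length = 1000, chromSizes = NULL) {
  gr <- genes@ranges
  t0 <- tss(genes)
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  s0 <- ifelse(plus, t0 - length, t0)
  e0 <- ifelse(plus, t0, t0 + length)
  s0c <- pmax(s0, 0)
  chr <- as.character(seqnames(gr))
  e0c <- if (is.null(chromSizes)) e0 else pmin(e0, chromSizes[chr])
  keep <- e0c > s0c
  out <- GRanges(chr[keep], IRanges(s0c[keep] + 1L, e0c[keep]),
                 strand = GenomicRanges::strand(gr)[keep])
  names(out) <- gr$gene_id[keep]
  out$clipped <- (e0 - s0)[keep] - (e0c - s0c)[keep]
  out
}

#' Gene-body regions
#'
#' The gene interval itself, named by gene id, for use as the region source
#' of [stateProportionProfile()] (state occupancy across coding regions).
#'
#' @param genes A [GeneModelSet].
#' @return GRanges named by gene id.
#' @export
geneBodyRegions <- function(genes) {
  out <- granges(genes, use.mcols = FALSE)
  names(out) <- genes@ranges$gene_id
  out
}

#' Mean state proportions per gene bin
#'
#' For each bin of genes, the bp-weighted proportion of each chromatin
#' state over the member genes' regions (promoters or gene bodies):
#' pooled state bp divided by pooled assigned bp, so each row sums to 1.
#' Unassigned bp is excluded from the denominator; genes whose region is
#' entirely unassigned (or who lack a region) are excluded and counted in
#' attribute `n_excluded`.
#'
#' @param regions GRanges named by gene id (e.g. [promoterRegions()]).
#' @param bins Named integer vector gene -> bin from [binGenes()], or a
#'   named vector of group labels.
#' @param seg A [StateSegmentation].
#' @return Matrix bins x states of proportions, with attribute
#'   `n_excluded`.
#' @export
stateProportionProfile <- function(regions, bins, seg) {
  st <- seg@states
  gr <- seg@ranges
  common <- intersect(names(bins), names(regions))
  excluded <- length(bins) - length(common)
  bins <- bins[common]
  regions <- regions[common]
  lev <- sort(unique(bins))
  out <- matrix(0, length(lev), length(st),
                dimnames = list(as.character(lev), st))
  hits <- GenomicRanges::findOverlaps(regions, gr, ignore.strand = TRUE)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    regions[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  stateOf <- gr$state[S4Vectors::subjectHits(hits)]
  binOf <- bins[S4Vectors::queryHits(hits)]
  keep <- stateOf != UNASSIGNED
  bp <- tapply(w[keep],
               list(factor(as.character(binOf[keep]),
                           levels = as.character(lev)),
                    factor(stateOf[keep], levels = st)),
               sum, default = 0)
  out[rownames(bp), colnames(bp)] <- bp
  rs <- rowSums(out)
  out <- out / ifelse(rs > 0, rs, 1)
  structure(out, n_excluded = excluded)
}

#' Call tissue-specific genes
#'
#' A gene is specific to tissue `t` when its mean TPM in `t` is at least
#' `fold` times its mean across all tissues (two-fold by default).  Genes
#' qualifying in several tissues are all reported, flagged by
#' `n_tissues`; genes with zero overall mean are never called.
#'
#' @param expr SummarizedExperiment with a `tissue` column, or matrix with
#'   `tissue_rep` sample names.
#' @param fold Fold-change threshold (default 2).
#' @return data.frame `gene_id`, `tissue`, `ratio`, `n_tissues` (one row
#'   per qualifying gene-tissue pair).
#' @export
tissueSpecificGenes <- function(expr, fold = 2) {
  m <- .tpmMatrix(expr)
  tis <- .tissueTags(expr)
  lev <- unique(tis)
  tm <- vapply(lev, function(t) rowMeans(m[, tis == t, drop = FALSE]),
               numeric(nrow(m)))
  if (!is.matrix(tm))
    tm <- matrix(tm, nrow = nrow(m), dimnames = list(rownames(m), lev))
  mu <- rowMeans(tm)
  hit <- tm >= fold * mu & mu > 0
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(gene_id = character(), tissue = character(),
                      ratio = numeric(), n_tissues = integer()))
  nhit <- rowSums(hit)
  out <- data.frame(gene_id = rownames(m)[idx[, 1]],
                    tissue = lev[idx[, 2]],
                    ratio = tm[idx] / mu[idx[, 1]],
                    n_tissues = nhit[idx[, 1]])
  out[order(out$gene_id, out$tissue), , drop = FALSE]
}

#' Summaries of asinh(TPM) per gene group and condition
#'
#' For two expression matrices over a shared gene universe (e.g. wild type
#' and mutant) and a gene grouping, reports n, mean, median and quartiles
#' of `asinh(TPM)` per group and condition.  Empty groups are skipped with
#' a warning.
#'
#' @param exprA,exprB Two expression objects (SummarizedExperiment or
#'   matrix) sharing gene ids.
#' @param geneGroups Named vector gene -> group label.
#' @param labels Length-2 condition labels (default `c("A", "B")`).
#' @return data.frame: group, condition, n, mean, median, q25, q75.
#' @export
groupExpressionSummary <- function(exprA, exprB, geneGroups,
                                   labels = c("A", "B")) {
  mats <- list(.tpmMatrix(exprA), .tpmMatrix(exprB))
  out <- list()
  for (g in unique(geneGroups)) {
    genes <- names(geneGroups)[geneGroups == g]
    for (i in 1:2) {
      m <- mats[[i]]
      v <- asinh(as.vector(m[intersect(genes, rownames(m)), , drop = FALSE]))
      if (length(v) == 0L) {
        warning("group '", g, "' is empty in condition ", labels[i],
                "; skipped")
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, condition = labels[i], n = length(v), mean = mean(v),
        median = q[2], q25 = q[1], q75 = q[3])
    }
  }
  do.call(rbind, out)
}
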