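#' @include methods.R
NULL

## One global seed expands into independent per-stream child seeds so
## regenerating one layer does not perturb the others.
.childSeeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("genome", "peaks", "expression", "coexpr"))
}

#' Default emission palette of the synthetic epigenome
#'
#' Nine states over ten marks, emulating the canonical plant chromatin
#' domains: a promoter/NFR intergenic state (I1) and a background
#' intergenic filler (I2) with uniformly low emissions; a +1-nucleosome
#' state E1 (H2A.Z + H3K4me3) grading into gene-body states E2-E4
#' (H3K36me3, H2Bub, H2A.X); facultative heterochromatin F1 (H3K27me3 with
#' H2A.Z + H2Aub); and pericentromeric heterochromatin H1/H2 (H3K9me2,
#' H3K27me1, H2A.W).
#'
#' @return Matrix states x marks of emission probabilities.
#' @export
defaultEmissionPalette <- function() {
  marks <- c("H3K4me3", "H3K36me3", "H2Bub", "H2A.Z", "H2A.X",
             "H3K27me3", "H2Aub", "H3K9me2", "H3K27me1", "H2A.W")
  p <- rbind(
    I1 = c(0.15, 0.02, 0.02, 0.10, 0.05, 0.05, 0.05, 0.02, 0.02, 0.02),
    I2 = c(0.05, 0.02, 0.02, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    E1 = c(0.90, 0.30, 0.20, 0.85, 0.30, 0.05, 0.10, 0.02, 0.02, 0.02),
    E2 = c(0.50, 0.70, 0.40, 0.40, 0.60, 0.05, 0.05, 0.02, 0.02, 0.02),
    E3 = c(0.20, 0.80, 0.60, 0.15, 0.70, 0.05, 0.05, 0.02, 0.02, 0.02),
    E4 = c(0.10, 0.90, 0.70, 0.10, 0.80, 0.05, 0.05, 0.02, 0.02, 0.02),
    F1 = c(0.30, 0.10, 0.05, 0.60, 0.10, 0.85, 0.60, 0.05, 0.10, 0.05),
    H1 = c(0.02, 0.02, 0.02, 0.02, 0.05, 0.10, 0.05, 0.90, 0.70, 0.85),
    H2 = c(0.02, 0.02, 0.02, 0.02, 0.05, 0.05, 0.05, 0.70, 0.40, 0.60))
  colnames(p) <- marks
  p
}

#' Default positional state profile around the TSS
#'
#' Per-offset categorical distributions over states for the gene footprint:
#' promoter bins are the NFR state I1, the TSS bin mixes I1 and the
#' +1-nucleosome state E1, and E1-E4 grade from the first nucleosome into
#' the gene body (planted modes +1, +2, +3, +4).
#'
#' @param promoterBins,bodyBins Footprint geometry in bins.
#' @return Matrix offsets x states; rows sum to 1; row names are signed
#'   bin offsets from the TSS.
#' @export
defaultPositionalProfile <- function(promoterBins = 2, bodyBins = 5) {
  states <- c("I1", "E1", "E2", "E3", "E4")
  offs <- seq(-promoterBins, bodyBins - 1L)
  m <- matrix(0, length(offs), length(states),
              dimnames = list(as.character(offs), states))
  m[as.character(seq(-promoterBins, -1L)), "I1"] <- 1
  m["0", c("I1", "E1")] <- c(0.25, 0.75)
  if (bodyBins >= 2) m["1", c("E1", "E2")] <- c(0.85, 0.15)
  if (bodyBins >= 3) m["2", c("E1", "E2", "E3")] <- c(0.05, 0.85, 0.10)
  if (bodyBins >= 4) m["3", c("E2", "E3", "E4")] <- c(0.10, 0.85, 0.05)
  if (bodyBins >= 5) m["4", c("E3", "E4")] <- c(0.05, 0.95)
  if (bodyBins > 5) for (o in 5:(bodyBins - 1L)) m[as.character(o), "E4"] <- 1
  m
}

#' Configuration of the synthetic epigenome
#'
#' Bundles and validates every tunable of the generator.  The defaults
#' describe the standard study conditions used throughout the test suite:
#' a 1 Mb genome (2 chromosomes of 500 kb, 200 bp bins), 500 genes, a
#' pericentromeric TE compartment of 10% of each chromosome split between
#' two heterochromatin states, 30 TFs in 5 preference groups at preference
#' weight 0.8, and a 5-tissue expression panel with log-normal baselines,
#' a 20% silent and 20% tissue-specific gene fraction at fold 4.
#'
#' @param seed Global seed; expanded into per-stream child seeds.
#' @param nChroms,chromLength,binSize Genome geometry.
#' @param geneCount Total genes; `promoterBins`/`bodyBins` set the
#'   footprint, `minSpacingBins` the minimum gap between footprints.
#' @param teFraction Central fraction of each chromosome given to the TE /
#'   heterochromatin compartment; `hetMix` splits it between H states
#'   (innermost first).
#' @param profile Positional profile matrix (see
#'   [defaultPositionalProfile()]).
#' @param emissionPalette Emission matrix over all states (see
#'   [defaultEmissionPalette()]).
#' @param fillerState Label of the background intergenic state.
#' @param couplingState Facultative state planted in gene bodies with
#'   probability increasing as expression decreases; `NULL` disables the
#'   expression-chromatin coupling.
#' @param nTfs,nGroups,groupStates,nPeaks,preferenceWeight,
#'   functionalTargets,peakWidth TF peak layer: number of TFs, planted
#'   preference groups and their preferred states, peaks per TF, the
#'   fraction of peaks planted in the preferred state near functional
#'   target genes, targets per TF, and the peak width range in bp.
#' @param nTissues,repsPerTissue,meanlog,sdlog,tissueSpecificFraction,
#'   silentFraction,fold,noiseSd,referenceTissue Expression layer:
#'   log-normal TPM baseline, gene class fractions, tissue-specific fold
#'   effect (must be >= 2), multiplicative log-normal noise sd, and the
#'   tissue used for TPM ranking.
#' @param functionalCeiling,negativeWindow Co-expression layer: functional
#'   targets receive ranks strictly below the ceiling; the negative tail
#'   is the top `negativeWindow` ranks.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1,
                            nChroms = 2, chromLength = 500000, binSize = 200,
                            geneCount = 500, promoterBins = 2, bodyBins = 5,
                            minSpacingBins = 1,
                            teFraction = 0.1, hetMix = c(H1 = 0.65, H2 = 0.35),
                            profile = defaultPositionalProfile(promoterBins,
                                                               bodyBins),
                            emissionPalette = defaultEmissionPalette(),
                            fillerState = "I2",
                            couplingState = "F1",
                            nTfs = 30, nGroups = 5,
                            groupStates = c("I1", "E1", "E2", "E3", "F1"),
                            nPeaks = 60, preferenceWeight = 0.8,
                            functionalTargets = 40, peakWidth = c(200, 400),
                            nTissues = 5, repsPerTissue = 2,
                            meanlog = 2, sdlog = 1.5,
                            tissueSpecificFraction = 0.2,
                            silentFraction = 0.2, fold = 4, noiseSd = 0.2,
                            referenceTissue = "tissue1",
                            functionalCeiling = 100, negativeWindow = 50) {
  cfg <- mget(ls(environment()))
  if (binSize <= 0) stop("binSize must be positive")
  if (preferenceWeight < 0 || preferenceWeight > 1)
    stop("preferenceWeight must lie in [0, 1]")
  if (tissueSpecificFraction > 0 && fold < 2)
    stop("tissue-specific genes require fold >= 2")
  if (abs(sum(hetMix) - 1) > 1e-9) stop("hetMix must sum to 1")
  bad <- setdiff(colnames(profile), rownames(emissionPalette))
  if (length(bad))
    stop("profile references states absent from the palette: ",
         paste(bad, collapse = ", "))
  if (!fillerState %in% rownames(emissionPalette))
    stop("fillerState absent from the palette")
  if (!is.null(couplingState) &&
      !couplingState %in% rownames(emissionPalette))
    stop("couplingState absent from the palette")
  if (any(abs(rowSums(profile) - 1) > 1e-9))
    stop("profile rows must sum to 1")
  if (length(groupStates) != nGroups)
    stop("groupStates must have one state per group")
  structure(cfg, class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat("SyntheticConfig:", x$nChroms, "x", x$chromLength, "bp,",
      x$geneCount, "genes,", x$nTfs, "TFs in", x$nGroups, "groups\n")
  invisible(x)
}

## Gene slot layout per chromosome: start bins of equally wide slots on
## both chromosome arms, avoiding the central het compartment.
.geneSlots <- function(nBins, hetStart, hetEnd, slotW, n) {
  arms <- list(c(0L, hetStart), c(hetEnd, nBins))
  slots <- unlist(lapply(arms, function(a) {
    k <- (a[2] - a[1]) %/% slotW
    if (k > 0) a[1] + slotW * (seq_len(k) - 1L) else integer(0)
  }))
  if (length(slots) < n)
    stop("cannot place ", n, " genes per chromosome (capacity ",
         length(slots), "); reduce geneCount or the gene footprint")
  idx <- unique(round(seq(1, length(slots), length.out = n)))
  while (length(idx) < n) idx <- sort(union(idx, setdiff(seq_along(slots),
                                                         idx)[1]))
  slots[idx[seq_len(n)]]
}

#' Generate the synthetic genome layer
#'
#' Builds gene models, a chromatin-state segmentation and the emission
#' matrix with planted ground truth.  Each chromosome carries a central
#' TE/heterochromatin compartment (H states ordered from the centromere
#' outwards) flanked by gene arms; each gene's footprint bins are labelled
#' by sampling the positional profile (strand-aware mirroring for `-`
#' genes), with body bins swapped for the coupling state with probability
#' increasing as the gene's planted expression baseline decreases.
#' Remaining bins take the intergenic filler state.  Deterministic for a
#' fixed config.
#'
#' @param config A [syntheticConfig()].
#' @return list: `genes` ([GeneModelSet], protein-coding plus TE records
#'   over the het compartment), `seg` ([StateSegmentation]), `emissions`
#'   ([EmissionMatrix]), `truth` (planted ground truth).
#' @export
generateGenome <- function(config) {
  cfg <- config
  set.seed(.childSeeds(cfg$seed)[["genome"]])
  bs <- cfg$binSize
  nBins <- as.integer(cfg$chromLength %/% bs)
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  chromSizes <- stats::setNames(rep(nBins * bs, cfg$nChroms), chroms)
  profile <- cfg$profile
  offs <- as.integer(rownames(profile))
  footprint <- length(offs)
  slotW <- footprint + cfg$minSpacingBins
  hetBins <- as.integer(round(nBins * cfg$teFraction))
  hetStart <- (nBins - hetBins) %/% 2L
  hetEnd <- hetStart + hetBins
  perChrom <- rep(cfg$geneCount %/% cfg$nChroms, cfg$nChroms)
  extra <- cfg$geneCount - sum(perChrom)
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L

  ## planted expression classes and baselines (reused by the expression
  ## layer through truth, so the layers stay independent)
  n <- cfg$geneCount
  ids <- sprintf("g%04d", seq_len(n))
  cls <- sample(c("silent", "tissue_specific", "ubiquitous"), n,
                replace = TRUE,
                prob = c(cfg$silentFraction, cfg$tissueSpecificFraction,
                         1 - cfg$silentFraction - cfg$tissueSpecificFraction))
  tissues <- paste0("tissue", seq_len(cfg$nTissues))
  owner <- ifelse(cls == "tissue_specific",
                  sample(tissues, n, replace = TRUE), NA)
  baseline <- ifelse(cls == "silent", 0,
                     stats::rlnorm(n, cfg$meanlog, cfg$sdlog))
  ## repression fraction: squared complementary rank of the baseline, so
  ## silent genes are almost fully covered by the coupling state and the
  ## coverage decays smoothly with expression
  pct <- (rank(baseline, ties.method = "first") - 0.5) / n
  fRep <- (1 - pct)^2

  gi <- 0L
  geneRows <- list()
  teRows <- list()
  binLists <- list()
  hetStates <- names(cfg$hetMix)
  for (ci in seq_len(cfg$nChroms)) {
    chrom <- chroms[ci]
    bins <- rep(cfg$fillerState, nBins)
    ## het compartment: innermost state first, flanks outward
    widths <- round(hetBins * cfg$hetMix)
    widths[length(widths)] <- hetBins - sum(widths[-length(widths)])
    inner <- hetStart + (hetBins - widths[1]) %/% 2L
    bins[(inner + 1L):(inner + widths[1])] <- hetStates[1]
    if (length(hetStates) > 1L && widths[2] > 0) {
      left <- hetStart + seq_len(inner - hetStart)
      right <- (inner + widths[1] + 1L):hetEnd
      bins[c(left, right)] <- hetStates[2]
    }
    if (hetBins > 0)
      teRows[[chrom]] <- data.frame(chrom = chrom,
                                    s0 = hetStart * bs, e0 = hetEnd * bs)
    slots <- .geneSlots(nBins, hetStart, hetEnd, slotW, perChrom[ci])
    for (slot in slots) {
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      ## TSS bin such that the whole footprint sits inside the slot
      tbin <- if (strand == "+") slot + cfg$promoterBins
              else slot + cfg$bodyBins - 1L
      dir <- if (strand == "+") 1L else -1L
      for (j in seq_along(offs)) {
        b <- tbin + offs[j] * dir
        s <- sample(colnames(profile), 1L, prob = profile[j, ])
        if (!is.null(cfg$couplingState) && offs[j] >= 0 &&
            stats::runif(1) < fRep[gi])
          s <- cfg$couplingState
        bins[b + 1L] <- s
      }
      bodyStart <- if (strand == "+") tbin else tbin - cfg$bodyBins + 1L
      s0 <- bodyStart * bs
      e0 <- (bodyStart + cfg$bodyBins) * bs
      geneRows[[gi]] <- data.frame(gene_id = ids[gi], chrom = chrom,
                                   s0 = s0, e0 = e0, strand = strand,
                                   tss_bin = tbin)
    }
    binLists[[chrom]] <- bins
  }

  ## bins -> run-length intervals
  segRows <- lapply(chroms, function(chrom) {
    r <- rle(binLists[[chrom]])
    e0 <- cumsum(r$lengths) * bs
    s0 <- c(0, e0[-length(e0)])
    data.frame(chrom = chrom, s0 = s0, e0 = pmin(e0, chromSizes[[chrom]]),
               state = r$values)
  })
  segDf <- do.call(rbind, segRows)
  segGr <- GRanges(segDf$chrom, IRanges(segDf$s0 + 1L, segDf$e0),
                   state = segDf$state)
  seg <- StateSegmentation(segGr, states = rownames(cfg$emissionPalette),
                           chromSizes = chromSizes, binSize = bs)

  gdf <- do.call(rbind, geneRows)
  ggr <- GRanges(gdf$chrom, IRanges(gdf$s0 + 1L, gdf$e0),
                 strand = gdf$strand, gene_id = gdf$gene_id,
                 feature_class = "protein_coding")
  if (length(teRows)) {
    tdf <- do.call(rbind, teRows)
    tgr <- GRanges(tdf$chrom, IRanges(tdf$s0 + 1L, tdf$e0), strand = "+",
                   gene_id = paste0("TE_", seq_len(nrow(tdf))),
                   feature_class = "TE")
    ggr <- c(ggr, tgr)
  }
  genes <- GeneModelSet(ggr)

  plantedMode <- apply(profile, 2, function(p) offs[which.max(p)])
  cov <- genomeCoverage(seg)
  truth <- list(
    config = cfg,
    chromSizes = chromSizes,
    centromeres = stats::setNames(rep((nBins * bs) / 2, cfg$nChroms),
                                  chroms),
    genes = data.frame(gene_id = ids, class = cls, tissue = owner,
                       baseline = baseline, repression = fRep,
                       stringsAsFactors = FALSE),
    states = data.frame(state = rownames(cfg$emissionPalette),
                        planted_mode = plantedMode[
                          rownames(cfg$emissionPalette)],
                        realized_fraction = cov[
                          rownames(cfg$emissionPalette)] / 100,
                        row.names = NULL),
    het = list(fraction = cfg$teFraction, mix = cfg$hetMix))
  list(genes = genes, seg = seg,
       emissions = EmissionMatrix(cfg$emissionPalette), truth = truth)
}

## Footprint bins (absolute bin indices, TSS-relative order) of one gene.
.geneFootprintBins <- function(tssBin, strand, offs) {
  tssBin + offs * (if (strand == "+") 1L else -1L)
}

#' Generate TF peak sets with planted state preferences
#'
#' For each TF, `ceiling(preferenceWeight * nPeaks)` peaks are planted in
#' bins of the TF's preferred state inside the footprints of its
#' functional target genes (genes drawn among those actually carrying the
#' state); the remaining peaks fall uniformly on the genome.  Peak widths
#' are drawn uniformly from the configured range and centers are jittered
#' within their bin.
#'
#' @param genome Output of [generateGenome()].
#' @param config The same [syntheticConfig()].
#' @return list: `peaks` (list of [PeakSet]s) and `truth` (the genome
#'   truth extended with a `tfs` table and `functionalTargets` list).
#' @export
generatePeaks <- function(genome, config) {
  cfg <- config
  set.seed(.childSeeds(cfg$seed)[["peaks"]])
  seg <- genome$seg
  bs <- cfg$binSize
  bstates <- .binStates(seg)
  offs <- as.integer(rownames(cfg$profile))
  gdf <- genome$truth$genes
  ggr <- genome$genes@ranges
  pc <- ggr[ggr$feature_class == "protein_coding"]
  gchrom <- as.character(seqnames(pc))
  gstrand <- as.character(GenomicRanges::strand(pc))
  tssBin <- .anchorBin(tss(genome$genes)[ggr$feature_class ==
                                           "protein_coding"],
                       gstrand, bs)
  chromSizes <- seg@chromSizes
  if (cfg$nTfs == 0L) return(list(peaks = list(), truth = genome$truth))
  group <- rep(seq_len(cfg$nGroups), length.out = cfg$nTfs)
  group <- sort(group)
  tfIds <- sprintf("TF%02d", seq_len(cfg$nTfs))
  absent <- setdiff(cfg$groupStates, unique(unlist(lapply(bstates, unique))))
  if (length(absent))
    stop("preferred state(s) absent from segmentation: ",
         paste(absent, collapse = ", "))
  ## per-gene footprint state lookup
  footBins <- lapply(seq_along(pc), function(i)
    .geneFootprintBins(tssBin[i], gstrand[i], offs))
  footStates <- lapply(seq_along(pc), function(i)
    bstates[[gchrom[i]]][footBins[[i]] + 1L])
  peaks <- vector("list", cfg$nTfs)
  names(peaks) <- tfIds
  targets <- vector("list", cfg$nTfs)
  names(targets) <- tfIds
  for (t in seq_len(cfg$nTfs)) {
    pref <- cfg$groupStates[group[t]]
    carriers <- which(vapply(footStates, function(s) pref %in% s,
                             logical(1)))
    nf <- min(cfg$functionalTargets, length(carriers))
    fg <- sort(sample(carriers, nf))
    targets[[t]] <- pc$gene_id[fg]
    nPlant <- if (nf > 0) ceiling(cfg$preferenceWeight * cfg$nPeaks) else 0L
    nPlant <- min(nPlant, cfg$nPeaks)
    rows <- list()
    if (nPlant > 0) {
      host <- fg[1L + (seq_len(nPlant) - 1L) %% nf]
      for (i in seq_len(nPlant)) {
        g <- host[i]
        cand <- footBins[[g]][footStates[[g]] == pref]
        b <- if (length(cand) == 1L) cand else sample(cand, 1L)
        center <- b * bs + sample.int(bs, 1L) - 1L
        w <- sample(seq(cfg$peakWidth[1], cfg$peakWidth[2]), 1L)
        s0 <- max(0, center - w %/% 2)
        e0 <- min(chromSizes[[gchrom[g]]], s0 + w)
        rows[[length(rows) + 1L]] <- data.frame(chrom = gchrom[g],
                                                s0 = s0, e0 = e0)
      }
    }
    nBg <- cfg$nPeaks - nPlant
    if (nBg > 0) {
      chrom <- sample(names(chromSizes), nBg, replace = TRUE,
                      prob = chromSizes / sum(chromSizes))
      w <- sample(seq(cfg$peakWidth[1], cfg$peakWidth[2]), nBg,
                  replace = TRUE)
      center <- floor(stats::runif(nBg) * chromSizes[chrom])
      s0 <- pmax(0, center - w %/% 2)
      e0 <- pmin(chromSizes[chrom], s0 + w)
      rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, s0 = s0,
                                              e0 = e0)
    }
    if (length(rows)) {
      d <- do.call(rbind, rows)
      gr <- GRanges(d$chrom, IRanges(d$s0 + 1L, d$e0))
    } else gr <- GRanges()
    peaks[[t]] <- PeakSet(tfIds[t], "chip", gr)
  }
  truth <- genome$truth
  truth$tfs <- data.frame(tf_id = tfIds, group = group,
                          preferred_state = cfg$groupStates[group],
                          stringsAsFactors = FALSE)
  truth$functionalTargets <- targets
  list(peaks = peaks, truth = truth)
}

#' Generate the TPM expression matrix
#'
#' Uses the planted baselines from the genome truth: silent genes are
#' exactly 0 in every sample; tissue-specific genes have their baseline
#' multiplied by the configured fold in their owning tissue; every
#' non-silent value gets multiplicative log-normal noise of sd `noiseSd`
#' (0 gives noise-free means).
#'
#' @param truth Truth list from [generateGenome()]/[generatePeaks()].
#' @param config The same [syntheticConfig()].
#' @return SummarizedExperiment with assay `tpm` and tissue tags.
#' @export
generateExpression <- function(truth, config) {
  cfg <- config
  if (cfg$tissueSpecificFraction > 0 && cfg$fold < 2)
    stop("tissue-specific genes require fold >= 2")
  set.seed(.childSeeds(cfg$seed)[["expression"]])
  g <- truth$genes
  tissues <- paste0("tissue", seq_len(cfg$nTissues))
  samples <- as.vector(t(outer(tissues, seq_len(cfg$repsPerTissue),
                               paste, sep = "_")))
  m <- matrix(0, nrow(g), length(samples),
              dimnames = list(g$gene_id, samples))
  for (j in seq_along(samples)) {
    t <- sub("_[0-9]+$", "", samples[j])
    mu <- g$baseline *
      ifelse(!is.na(g$tissue) & g$tissue == t, cfg$fold, 1)
    noise <- if (cfg$noiseSd > 0)
      exp(stats::rnorm(nrow(g), 0, cfg$noiseSd)) else 1
    m[, j] <- mu * noise
  }
  makeExpression(m, rep(tissues, each = cfg$repsPerTissue))
}

#' Generate an ATTED-style co-expression rank table
#'
#' Per TF, every protein-coding gene receives an integer rank 1..G;
#' functional target genes get ranks drawn strictly below the functional
#' ceiling, all other genes the remaining ranks in random order.
#'
#' @param truth Truth list from [generatePeaks()] (needs
#'   `functionalTargets`).
#' @param config The same [syntheticConfig()].
#' @return data.frame `tf_id`, `gene_id`, `score`.
#' @export
generateCoexpression <- function(truth, config) {
  cfg <- config
  set.seed(.childSeeds(cfg$seed)[["coexpr"]])
  if (is.null(truth$functionalTargets))
    stop("truth lacks functional targets; run generatePeaks first")
  genes <- truth$genes$gene_id
  G <- length(genes)
  out <- list()
  for (tf in names(truth$functionalTargets)) {
    fg <- truth$functionalTargets[[tf]]
    nf <- length(fg)
    if (nf >= cfg$functionalCeiling)
      stop("functionalCeiling must exceed the functional target count")
    low <- sample(seq_len(cfg$functionalCeiling - 1L), nf)
    rest <- setdiff(seq_len(G), low)
    score <- integer(G)
    names(score) <- c(fg, sample(setdiff(genes, fg)))
    score[seq_len(nf)] <- low
    score[nf + seq_len(G - nf)] <- sample(rest)
    out[[tf]] <- data.frame(tf_id = tf, gene_id = names(score),
                            score = unname(score))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$tf_id, res$gene_id), ]
}

#' Generate the full synthetic data set
#'
#' Runs all generator layers under one config: genome, TF peaks,
#' expression and co-expression, with the planted truth.
#'
#' @param config A [syntheticConfig()].
#' @return list: genes, seg, emissions, peaks, expression, coexpr, truth.
#' @export
generateSyntheticData <- function(config = syntheticConfig()) {
  genome <- generateGenome(config)
  pk <- generatePeaks(genome, config)
  expr <- generateExpression(pk$truth, config)
  coex <- generateCoexpression(pk$truth, config)
  list(genes = genome$genes, seg = genome$seg, emissions = genome$emissions,
       peaks = pk$peaks, expression = expr, coexpr = coex,
       truth = pk$truth)
}

#' Serialize the planted truth as JSON
#' @param truth Truth list.
#' @param path Output path.
#' @export
writeTruth <- function(truth, path) {
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
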