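test_that("genome coverage follows the bp formula", {
  seg <- segFromBins(list(chr1 = c(rep("A", 10), rep("B", 40))),
                     binSize = 200)
  cov <- genomeCoverage(seg)
  expect_equal(unname(cov["A"]), 20)
  expect_equal(unname(cov["B"]), 80)
  one <- segFromBins(list(chr1 = rep("A", 5)))
  expect_equal(unname(genomeCoverage(one)), 100)
})

test_that("feature composition resolves classes and sums to 1", {
  seg <- segFromBins(list(chr1 = c("A", "A", "B", "B", "C")), binSize = 200)
  genes <- genesFromDf(data.frame(
    gene_id = c("g1", "t1"), chrom = "chr1",
    s0 = c(0, 400), e0 = c(400, 800), strand = "+",
    feature_class = c("protein_coding", "TE")))
  comp <- featureComposition(seg, genes)
  expect_equal(unname(rowSums(comp)), rep(1, 3))
  expect_equal(comp["A", "protein_coding"], 1)   # fully genic
  expect_equal(comp["B", "TE"], 1)
  expect_equal(comp["C", "intergenic"], 1)       # fully outside annotation
})

test_that("neighbourhood enrichment gives forced ratios and flat baselines", {
  ## uniform one-state genome: enrichment 1 everywhere
  seg <- segFromBins(list(chr1 = rep("A", 100)))
  anchors <- data.frame(chrom = "chr1", pos = c(4000, 10000),
                        strand = c("+", "-"))
  nb <- neighbourhoodEnrichment(seg, anchors, L = 5)
  expect_true(all(nb$enrichment == 1))

  ## every +1 bin is E1 and E1 covers 1/10 of the genome -> enrichment 10
  bins <- rep("B", 100)
  tssBins <- c(10, 30, 50, 70, 90)
  bins[tssBins + 1 + 1] <- "E1"               # +1 bin of each '+' anchor
  bins[setdiff(which(bins == "E1"), 0)]       # no-op; keep layout explicit
  extraE1 <- setdiff(seq(2, 100, by = 20), tssBins + 2)
  bins[extraE1[seq_len(10 - length(tssBins))]] <- "E1"
  seg <- segFromBins(list(chr1 = bins))
  stopifnot(sum(bins == "E1") == 10)
  anchors <- data.frame(chrom = "chr1", pos = tssBins * 200, strand = "+")
  nb <- neighbourhoodEnrichment(seg, anchors, L = 2)
  expect_equal(nb$enrichment["E1", "1"], 10)
})

test_that("neighbourhood enrichment matches the anchor-walk oracle", {
  set.seed(7)
  for (trial in 1:5) {
    seg <- randomSegmentation(nStates = 3, maxBins = 80)
    sizes <- chromSizes(seg)
    anchors <- data.frame(
      chrom = sample(names(sizes), 12, replace = TRUE),
      strand = sample(c("+", "-"), 12, replace = TRUE))
    anchors$pos <- vapply(anchors$chrom, function(c)
      sample.int(sizes[[c]] - 1, 1), numeric(1)) + 1
    nb <- neighbourhoodEnrichment(seg, anchors, L = 5)
    or <- oracleNeighbourhood(seg, anchors, L = 5)
    expect_equal(nb$fraction, or$fraction)
    expect_equal(nb$enrichment, or$enrichment)
    expect_equal(unname(nb$n), or$n)
  }
})

test_that("enrichment is invariant to anchor order and chromosome names", {
  set.seed(11)
  seg <- randomSegmentation(nStates = 3, maxBins = 60)
  sizes <- chromSizes(seg)
  anchors <- data.frame(
    chrom = sample(names(sizes), 10, replace = TRUE),
    strand = sample(c("+", "-"), 10, replace = TRUE))
  anchors$pos <- vapply(anchors$chrom, function(c)
    sample.int(sizes[[c]] - 400, 1), numeric(1)) + 200
  a <- neighbourhoodEnrichment(seg, anchors, L = 4)
  b <- neighbourhoodEnrichment(seg, anchors[sample(nrow(anchors)), ], L = 4)
  expect_equal(a$enrichment, b$enrichment)

  gr <- granges(seg, use.mcols = TRUE)
  ren <- c(chr1 = "scaffold_9", chr2 = "scaffold_1")
  gr2 <- GRanges(ren[as.character(seqnames(gr))], ranges(gr),
                 state = gr$state)
  seg2 <- StateSegmentation(gr2, chromSizes = setNames(sizes[names(ren)],
                                                       ren),
                            binSize = binSize(seg))
  anchors2 <- transform(anchors, chrom = ren[chrom])
  c2 <- neighbourhoodEnrichment(seg2, anchors2, L = 4)
  expect_equal(a$enrichment, c2$enrichment)
})

test_that("domain classification follows the rule cascade", {
  marks <- c("H3K9me2", "H3K27me3", "H2A.Z", "H2Aub", "H3K36me3")
  p <- rbind(het = c(0.9, 0.1, 0.1, 0.1, 0.1),
             nfr = c(0.1, 0.1, 0.15, 0.1, 0.1),
             fac = c(0.1, 0.8, 0.2, 0.1, 0.1),
             facPair = c(0.1, 0.1, 0.7, 0.6, 0.1),
             plusone = c(0.1, 0.1, 0.8, 0.1, 0.5),  # H2A.Z without H2Aub
             eu = c(0.1, 0.1, 0.1, 0.1, 0.9))
  colnames(p) <- marks
  comp <- matrix(0, 6, 4, dimnames = list(rownames(p),
    c("protein_coding", "TE", "other", "intergenic")))
  comp["het", "TE"] <- 0.8
  dom <- classifyDomains(EmissionMatrix(p), comp)
  expect_equal(setNames(dom$domain, dom$state),
               c(het = "H", nfr = "I", fac = "F", facPair = "F",
                 plusone = "E", eu = "E"))
  ## high het emission without TE support is not called H
  comp["het", "TE"] <- 0.1
  dom2 <- classifyDomains(EmissionMatrix(p), comp)
  expect_false(dom2$domain[dom2$state == "het"] == "H")
  ## missing all rule marks errors
  p2 <- p[, "H3K36me3", drop = FALSE]
  expect_error(classifyDomains(EmissionMatrix(p2), comp), "rule marks")
})

test_that("nomenclature numbers states by TSS offset with documented tie-break", {
  enr <- rbind(a = c(0, 0, 1, 5, 1), b = c(0, 5, 1, 0, 0),
               c = c(0, 5, 1, 0, 0))
  colnames(enr) <- as.character(-2:2)
  nb <- list(enrichment = enr)
  seg <- segFromBins(list(chr1 = c("a", "b", "c", "a", "b")))
  dom <- data.frame(state = c("a", "b", "c"), domain = "E", rule = "")
  out <- assignNomenclature(dom, nb, seg)
  ## argmax offsets: a -> +1; b and c tie at -1, same centroid, broken by
  ## label
  expect_equal(setNames(out$name, out$state),
               c(a = "E3", b = "E1", c = "E2"))
})

test_that("heterochromatin numbering follows centromere distance", {
  bins <- c(rep("H2", 10), rep("H1", 10), rep("H2", 10), rep("E", 20))
  seg <- segFromBins(list(chr1 = bins))
  dom <- data.frame(state = c("H1", "H2", "E"),
                    domain = c("H", "H", "E"), rule = "")
  nb <- list(enrichment = matrix(1, 3, 3,
    dimnames = list(c("H1", "H2", "E"), as.character(-1:1))))
  out <- assignNomenclature(dom, nb, seg, centromeres = c(chr1 = 3000))
  expect_equal(out$name[out$state == "H1"], "H1")
  expect_equal(out$name[out$state == "H2"], "H2")
  ## without centromeres, coverage decides (H2 covers more)
  out2 <- assignNomenclature(dom, nb, seg)
  expect_equal(out2$name[out2$state == "H2"], "H1")
})

test_that("chromosomal distribution tallies state bins per window", {
  bins <- c(rep("A", 250), rep("B", 250))
  seg <- segFromBins(list(chr1 = bins))   # 100 kb
  m <- chromosomalDistribution(seg, binwidth = 50000)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m[, "A"]), c(250, 0))
  expect_equal(unname(m[, "B"]), c(0, 250))
  empty <- chromosomalDistribution(seg, statesSubset = character(0),
                                   binwidth = 50000)
  expect_equal(ncol(empty), 0L)
  ## direct tally on a random genome
  set.seed(3)
  seg <- randomSegmentation(nStates = 3, maxBins = 100, nChroms = 1)
  m <- chromosomalDistribution(seg, binwidth = 10000)
  v <- perBpStates(seg)$chr1
  binStarts <- seq(1, length(v), by = 200)
  direct <- table(factor((binStarts[v[binStarts] == "S1"] - 1) %/% 10000,
                         levels = 0:(nrow(m) - 1)))
  expect_equal(unname(m[, "S1"]), as.integer(direct))
})

test_that("signal aggregation is bp-weighted with zero padding", {
  seg <- segFromBins(list(chr1 = c("A", "A", "B", "B")))
  const <- GRanges("chr1", IRanges(1, 800), score = 1)
  out <- aggregateSignalByState(seg, const)
  expect_equal(out$mean, c(1, 1))

  onA <- GRanges("chr1", IRanges(1, 400), score = 2)
  out <- aggregateSignalByState(seg, onA)
  expect_equal(out$mean[out$state == "A"], 2)
  expect_equal(out$mean[out$state == "B"], 0)

  expect_warning(aggregateSignalByState(seg,
    GRanges(c("chr1", "chrX"), IRanges(c(1, 1), c(400, 400)),
            score = c(1, 1))), "unknown chromosome")
  expect_error(aggregateSignalByState(seg,
    GRanges("chr1", IRanges(c(1, 200), c(400, 600)), score = c(1, 2))),
    "overlap")
})

test_that("signal aggregation matches the per-bp oracle", {
  set.seed(5)
  for (trial in 1:3) {
    seg <- randomSegmentation(nStates = 3, maxBins = 50, nChroms = 1)
    size <- chromSizes(seg)[[1]]
    cuts <- sort(sample(seq(200, size - 200, by = 100), 4))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, size)
    keep <- sample(length(starts), 3)
    sig <- GRanges("chr1", IRanges(starts[keep], ends[keep]),
                   score = round(runif(3), 3))
    out <- aggregateSignalByState(seg, sig)
    orc <- oracleSignalStats(seg, sig)
    expect_equal(out$mean, unname(orc[out$state, "mean"]))
    expect_equal(out$median, unname(orc[out$state, "median"]))
    expect_equal(out$q25, unname(orc[out$state, "q25"]))
    expect_equal(out$q75, unname(orc[out$state, "q75"]))
  }
})
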