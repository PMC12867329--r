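test_that("transition matrix: identity is diagonal, complement off-diagonal", {
  set.seed(21)
  seg <- randomSegmentation(nStates = 3, maxBins = 60)
  tm <- transitionMatrix(seg, seg)
  expect_equal(sum(tm) - sum(diag(tm)), 0)
  bp <- tapply(as.numeric(width(granges(seg))),
               as.character(granges(seg)$state), sum)
  expect_equal(unname(diag(tm)), as.numeric(bp[rownames(tm)]))

  a <- segFromBins(list(chr1 = c("X", "X", "Y", "Y")))
  b <- segFromBins(list(chr1 = c("Y", "Y", "X", "X")))
  tm2 <- transitionMatrix(a, b)
  expect_equal(diag(tm2), c(X = 0, Y = 0))
  expect_equal(tm2["X", "Y"], 400)
})

test_that("transition and Jaccard match the per-bp oracle", {
  set.seed(22)
  for (trial in 1:5) {
    segA <- randomSegmentation(nStates = 3, maxBins = 60, nChroms = 2)
    ## same chromosome sizes, independent labels
    binsB <- lapply(perBpStates(segA), function(v)
      sample(c("P", "Q", "R"), length(v) / 200, replace = TRUE))
    segB <- segFromBins(binsB)
    expect_equal(transitionMatrix(segA, segB), oracleTransition(segA, segB))
    expect_equal(unname(stateJaccard(segA, segB)),
                 unname(oracleJaccard(segA, segB)))
    ## symmetry under argument swap
    expect_equal(stateJaccard(segA, segB), t(stateJaccard(segB, segA)))
  }
})

test_that("Jaccard handles forced values", {
  a <- segFromBins(list(chr1 = c(rep("A", 100), rep("Z", 650))),
                   binSize = 200)
  b <- segFromBins(list(chr1 = c(rep("Z", 50), rep("B", 100),
                                 rep("Z", 600))), binSize = 200)
  ## A over [0,20000), B over [10000,30000): intersection 10000/union 30000
  J <- stateJaccard(a, b)
  expect_equal(J["A", "B"], 1 / 3)
  expect_equal(stateJaccard(a, a)["A", "A"], 1)
})

test_that("mark-removal returns best-match Jaccard per state", {
  full <- segFromBins(list(chr1 = c(rep("A", 4), rep("B", 4))))
  identicalRed <- segFromBins(list(chr1 = c(rep("a", 4), rep("b", 4))))
  split <- segFromBins(list(chr1 = c(rep("a1", 2), rep("a2", 2),
                                     rep("b", 4))))
  res <- markRemovalExperiment(full, list(same = identicalRed,
                                          split = split),
                               domains = data.frame(
                                 state = c("A", "B"),
                                 domain = c("E", "H"), rule = ""))
  same <- res$perState[res$perState$removal == "same", ]
  expect_equal(same$jaccard, c(1, 1))
  sp <- res$perState[res$perState$removal == "split", ]
  expect_equal(sp$jaccard[sp$full_state == "A"], 0.5)
  expect_equal(res$byDomain$mean_jaccard[
    res$byDomain$removal == "split" & res$byDomain$domain == "H"], 1)
})

test_that("emission clustering merges identical states first, orthogonal last", {
  pA <- rbind(s1 = c(1, 0, 0), s2 = c(0, 0, 1))
  pB <- rbind(t1 = c(1, 0, 0), t2 = c(0, 1, 0))
  colnames(pA) <- colnames(pB) <- c("m1", "m2", "m3")
  out <- emissionClustering(EmissionMatrix(pA), EmissionMatrix(pB))
  expect_equal(min(out$merges$height), 0)   # identical pair merges at 0
  d <- as.matrix(dist(out$matrix))
  expect_equal(d["A.s1", "B.t1"], 0)
  expect_equal(max(out$merges$height),
               max(as.matrix(dist(out$matrix))["A.s2", ]) * 0 +
                 out$merges$height[nrow(out$merges)])
  ## hand-computed pairwise distance oracle on the merged matrix
  expect_equal(d["A.s1", "A.s2"], sqrt(2))
  ## mark mapping renames B's namespace; too few common marks errors
  pB2 <- pB; colnames(pB2) <- c("x1", "x2", "x3")
  expect_error(suppressWarnings(
    emissionClustering(EmissionMatrix(pA), EmissionMatrix(pB2))),
    "common marks")
  out2 <- emissionClustering(EmissionMatrix(pA), EmissionMatrix(pB2),
                             markMap = c(x1 = "m1", x2 = "m2", x3 = "m3"))
  expect_equal(out2$matrix["B.t1", ], out$matrix["B.t1", ])
})

test_that("coordinate updates shift TSS strand-aware with documented ties", {
  genes <- genesFromDf(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    s0 = c(1000, 5000), e0 = c(3000, 7000), strand = c("+", "-")))
  ## anchor 10 bp downstream of gA's TSS (pos0 1010)
  anchors <- GRanges("chr1", IRanges(1011, 1011), strand = "+")
  out <- updateCoordinates(genes, anchors)
  expect_equal(out$shifts$gene_id, "gA")
  expect_equal(out$shifts$shift, 10)
  expect_equal(tss(out$genes)[1], 1010)

  ## '-' strand: anchor at pos0 6990, 10 bp into the gene; shift flipped
  anchors2 <- GRanges("chr1", IRanges(6991, 6991), strand = "-")
  out2 <- updateCoordinates(genes, anchors2)
  expect_equal(out2$shifts$shift, 10)
  expect_equal(tss(out2$genes)[2], 6990)

  ## equidistant anchor goes to the smaller gene id
  genes3 <- genesFromDf(data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1",
    s0 = c(1200, 800), e0 = c(2200, 1100), strand = "+"))
  anchors3 <- GRanges("chr1", IRanges(1001, 1001), strand = "+")
  out3 <- updateCoordinates(genes3, anchors3)
  expect_equal(out3$shifts$gene_id, "gA")

  ## beyond maxDistance: unmatched
  out4 <- updateCoordinates(genes, GRanges("chr1", IRanges(4000, 4000),
                                           strand = "+"))
  expect_equal(out4$unmatched, 1L)
  expect_equal(nrow(out4$shifts), 0L)
})

test_that("coordinate-set Jaccard counts tolerant agreement over the union", {
  a <- c(g1 = 100, g2 = 200, g3 = 300)
  expect_equal(coordinateSetJaccard(a, a), 1)
  b <- c(g1 = 150, g2 = 260, g4 = 500)
  expect_equal(coordinateSetJaccard(a, b, toleranceBp = 0), 0)
  expect_equal(coordinateSetJaccard(a, b, toleranceBp = 50), 0.25)
  expect_equal(coordinateSetJaccard(a, b, toleranceBp = 60), 0.5)
})
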