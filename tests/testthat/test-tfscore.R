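test_that("peak-state assignment uses the center bin", {
  seg <- segFromBins(list(chr1 = c("A", "B", "C", "D")))
  ## peak [100,301): center floor((100+301)/2) = 200 -> second bin
  ps <- PeakSet("TF1", "chip", GRanges("chr1", IRanges(101, 301)))
  expect_equal(assignPeakStates(ps, seg), "B")
  ## peak exactly one bin
  ps2 <- PeakSet("TF1", "chip", GRanges("chr1", IRanges(401, 600)))
  expect_equal(assignPeakStates(ps2, seg), "C")
  ## random peaks match a direct per-peak lookup
  set.seed(31)
  seg <- randomSegmentation(nStates = 4, maxBins = 50, nChroms = 2)
  sizes <- chromSizes(seg)
  chr <- sample(names(sizes), 30, replace = TRUE)
  s0 <- vapply(chr, function(c) sample.int(sizes[[c]] - 500, 1), numeric(1))
  ps3 <- PeakSet("TF1", "chip",
                 GRanges(chr, IRanges(s0 + 1, s0 + sample(100:400, 30,
                                                          replace = TRUE))))
  v <- perBpStates(seg)
  expected <- vapply(seq_len(30), function(i) {
    g <- granges(ps3)[i]
    center <- (start(g) - 1 + end(g)) %/% 2
    v[[as.character(seqnames(g))]][center + 1]
  }, character(1))
  expect_equal(assignPeakStates(ps3, seg), unname(expected))
})

test_that("occupancy enrichment implements (a/b)/(c/d) on bp", {
  ## forced arithmetic: state A = 1000 bp of 10000; peaks put 100 of their
  ## 200 bp in A -> (100/200)/(1000/10000) = 5
  seg <- segFromBins(list(chr1 = c(rep("A", 5), rep("B", 45))))
  pk <- PeakSet("TF1", "chip",
                GRanges("chr1", IRanges(c(901, 2001), c(1000, 2100))))
  occ <- occupancyEnrichment(pk, seg)
  expect_equal(occ$enrichment[occ$state == "A"], 5)
  expect_equal(sum(occ$a), occ$b[1])
  expect_equal(sum(unique(occ[c("state", "c")])$c), occ$d[1])

  ## conservation: peaks tiling the whole genome -> enrichment exactly 1
  all <- PeakSet("TF1", "chip", GRanges("chr1", IRanges(1, 10000)))
  occ2 <- occupancyEnrichment(all, seg)
  expect_equal(occ2$enrichment, rep(1, 2))
})

test_that("target annotation follows the promoter/body/nearest cascade", {
  seg <- segFromBins(list(chr1 = rep("A", 250)))   # 50 kb
  genes <- genesFromDf(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1",
    s0 = c(10000, 30000), e0 = c(12000, 32000), strand = c("+", "-")))
  mkpeak <- function(c0) GRanges("chr1", IRanges(c0 - 49, c0 + 50))
  pk <- PeakSet("TF1", "chip", sort(c(
    mkpeak(9800),    # 200 bp upstream of g1 TSS -> promoter
    mkpeak(11500),   # inside g1 body
    mkpeak(32500),   # 500 bp upstream of g2 ('-' strand promoter side)
    mkpeak(13000),   # 1 kb downstream of g1 -> nearest TSS g1... distal
    mkpeak(49000)))) # gene desert beyond maxDistance
  out <- annotateTargets(pk, genes, seg, maxDistance = 5000)
  a <- out$assignments[order(out$assignments$center), ]
  expect_equal(a$rule, c("promoter", "gene_body", "nearest_tss",
                         "promoter", "unassigned"))
  expect_equal(a$gene_id, c("g1", "g1", "g1", "g2", NA))
  expect_equal(sort(out$targetsByState$A), c("g1", "g2"))
})

test_that("co-expression filter applies strict rank thresholds", {
  co <- data.frame(tf_id = "TF1", gene_id = c("g1", "g2", "g3"),
                   score = c(100, 1999, 2000))
  f <- coexpressionFilter(co, "TF1")
  expect_equal(f$positive, c("g1", "g2"))     # strict <
  co2 <- data.frame(tf_id = "TF1", gene_id = paste0("g", 1:3),
                    score = c(100, 4500, 5000))
  f2 <- coexpressionFilter(co2, "TF1")
  expect_equal(f2$negative, c("g2", "g3"))    # > max(5000) - 1000
  expect_error(coexpressionFilter(co, "TFX"), "TFX")
})

test_that("activity score hits the forced points and enumeration oracle", {
  ## p = 1, OR = 0 -> score 0
  expect_equal(-log10(1) + log2(0 + 1), 0)
  res0 <- activityScore(list(S = character(0)), coexpressed = c("g1"),
                        universe = paste0("g", 1:10))
  expect_equal(res0$p_value, 1)
  expect_equal(res0$odds_ratio, 0)
  expect_equal(res0$raw_score, 0)
  ## p = 0.1, OR = 1 -> score 2 (formula check at the forced point)
  expect_equal(-log10(0.1) + log2(1 + 1), 2)

  ## p-values match exhaustive enumeration over fixed-margin tables
  universe <- paste0("g", 1:100)
  targets <- paste0("g", 1:10)            # m = 10
  coex <- paste0("g", c(1:5, 50:54))      # q = 10, k = 5
  res <- activityScore(list(S = targets), coex, universe)
  expect_equal(res$k, 5); expect_equal(res$m, 10); expect_equal(res$q, 10)
  expect_equal(res$p_value, enumFisherP(5, 10, 10, 100), tolerance = 1e-12)
  ## and the standard exact test agrees
  tab <- matrix(c(5, 5, 5, 85), 2)
  expect_equal(res$p_value,
               fisher.test(tab, alternative = "greater")$p.value)
  expect_equal(res$odds_ratio, (5 * 85) / (5 * 5))
  expect_equal(res$raw_score,
               -log10(res$p_value) + log2(res$odds_ratio + 1))
})

test_that("raw score is monotone non-decreasing in the overlap k", {
  universe <- paste0("g", 1:60)
  q <- 20
  coex <- universe[1:q]
  m <- 15
  prev <- -Inf
  for (k in 0:m) {
    targets <- c(universe[seq_len(k)], universe[q + seq_len(m - k)])
    r <- activityScore(list(S = targets), coex, universe)
    expect_gte(r$raw_score, prev)
    prev <- r$raw_score
  }
})

test_that("score matrix filter uses a strict threshold and row-max scaling", {
  mk <- function(tf, scores) data.frame(
    tf_id = tf, state = paste0("S", seq_along(scores)), k = 0, m = 0,
    q = 0, N = 0, p_value = 1, odds_ratio = 0, raw_score = scores,
    normalized_score = 0)
  res <- rbind(mk("lo", c(7.99, 3)), mk("edge", c(8, 4)),
               mk("hi", c(16, 8)))
  sm <- buildScoreMatrix(res)
  expect_equal(rownames(sm$matrix), c("edge", "hi"))
  expect_equal(sm$dropped$tf_id, "lo")
  expect_equal(unname(apply(sm$matrix, 1, max)), c(1, 1))
  expect_equal(unname(sm$matrix["hi", ]), c(1, 0.5))
  expect_error(buildScoreMatrix(mk("only", c(1, 2))), "threshold")
})

test_that("TF clustering recovers separable blocks deterministically", {
  m <- rbind(a1 = c(1, 1, 0, 0), a2 = c(1, 0.9, 0, 0),
             b1 = c(0, 0, 1, 1), b2 = c(0, 0, 0.9, 1))
  cl <- clusterTFs(m, k = 2)
  expect_equal(cl$clusters[["a1"]], cl$clusters[["a2"]])
  expect_equal(cl$clusters[["b1"]], cl$clusters[["b2"]])
  expect_false(cl$clusters[["a1"]] == cl$clusters[["b1"]])
  ## identical rows always co-cluster
  m2 <- rbind(x = c(1, 0), y = c(1, 0), z = c(0, 1))
  cl2 <- clusterTFs(m2, k = 2)
  expect_equal(cl2$clusters[["x"]], cl2$clusters[["y"]])
  expect_error(clusterTFs(m, k = 1), "k must be")
})

test_that("family enrichment matches the hypergeometric oracle", {
  cl <- setNames(c(1, 1, 1, 2, 2, 2), paste0("TF", 1:6))
  fam <- setNames(c("A", "A", "A", "B", "B", "B"), paste0("TF", 1:6))
  out <- familyEnrichment(cl, fam)
  aIn1 <- out[out$family == "A" & out$cluster == 1, ]
  expect_equal(aIn1$p_value, enumFisherP(3, 3, 3, 6), tolerance = 1e-12)
  expect_equal(min(out$p_value[out$family == "A"]), aIn1$p_value)
  ## uniformly spread family: OR approximately 1
  fam2 <- setNames(c("A", "B", "A", "B", "A", "B"), paste0("TF", 1:6))
  out2 <- familyEnrichment(cl, fam2)
  ## missing family labels pool as unknown
  out3 <- familyEnrichment(cl, fam[1:3])
  expect_true("unknown" %in% out3$family)
  expect_true(all(out$q_value >= out$p_value - 1e-12))
})

test_that("TSS histograms orient distances by gene strand", {
  genes <- genesFromDf(data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1",
    s0 = c(10000, 30000), e0 = c(12000, 32000), strand = c("+", "-")))
  ## peak at the '+' TSS exactly -> bin containing 0
  atTss <- PeakSet("a", "chip", GRanges("chr1", IRanges(9951, 10050)))
  ## center 150 bp beyond the '-' gene end = upstream -> -150
  upMinus <- PeakSet("b", "chip", GRanges("chr1", IRanges(32101, 32200)))
  h <- tssBindingHistogram(list(c1 = atTss, c2 = upMinus), genes,
                           window = 1000, nbins = 20)
  mids <- as.numeric(colnames(h))
  expect_equal(sum(h["c1", ]), 1)
  expect_equal(mids[which(h["c1", ] == 1)], 50)   # 0 falls in [0,100) bin
  expect_equal(sum(h["c2", ]), 1)
  expect_equal(mids[which(h["c2", ] == 1)], -150)
})
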