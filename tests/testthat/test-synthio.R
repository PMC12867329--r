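## Small config used where the full study conditions are not needed.
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(seed = 5, nChroms = 1, chromLength = 200000, geneCount = 60,
         nTfs = 10, nGroups = 5, nPeaks = 20, functionalTargets = 10,
         functionalCeiling = 30, negativeWindow = 10),
    list(...))
  do.call(syntheticConfig, args)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- generateSyntheticData(smallConfig())
  b <- generateSyntheticData(smallConfig())
  expect_identical(as.character(granges(a$seg)$state),
                   as.character(granges(b$seg)$state))
  expect_identical(SummarizedExperiment::assay(a$expression),
                   SummarizedExperiment::assay(b$expression))
  expect_identical(a$coexpr, b$coexpr)
  expect_identical(start(granges(a$peaks[[3]])),
                   start(granges(b$peaks[[3]])))
  ## and files are hash-stable
  f1 <- tempfile(); f2 <- tempfile()
  writeSegmentation(a$seg, f1); writeSegmentation(b$seg, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  ## a different seed changes the genome
  c <- generateSyntheticData(smallConfig(seed = 6))
  expect_false(identical(as.character(granges(a$seg)$state),
                         as.character(granges(c$seg)$state)))
})

test_that("a degenerate positional profile is planted exactly", {
  prof <- matrix(0, 4, 2, dimnames = list(as.character(-2:1),
                                          c("I1", "E1")))
  prof[c("-2", "-1", "0"), "I1"] <- 1
  prof["1", "E1"] <- 1
  cfg <- syntheticConfig(seed = 2, nChroms = 1, chromLength = 100000,
                         geneCount = 30, promoterBins = 2, bodyBins = 2,
                         profile = prof, couplingState = NULL,
                         nTfs = 0, nGroups = 5)
  g <- generateGenome(cfg)
  bs <- chromTF:::.binStates(g$seg)
  pc <- subsetGenes(g$genes, featureClass(g$genes) == "protein_coding")
  t0 <- tss(pc)
  str <- as.character(strand(granges(pc)))
  plusOne <- chromTF:::.anchorBin(t0, str, 200) +
    ifelse(str == "+", 1L, -1L)
  expect_true(all(bs$chr1[plusOne + 1] == "E1"))
})

test_that("planted genome fractions are recovered by coverage", {
  cfg <- syntheticConfig(seed = 3)   # 1 Mb study conditions
  g <- generateGenome(cfg)
  cov <- genomeCoverage(g$seg)
  ## het compartment fractions are deterministic: 10% split 65/35
  expect_equal(unname(cov["H1"]) / 100, 0.1 * 0.65, tolerance = 0.02)
  expect_equal(unname(cov["H2"]) / 100, 0.1 * 0.35, tolerance = 0.02)
  expect_equal(unname(sum(cov)), 100)
  ## truth records the realized fractions exactly
  expect_equal(g$truth$states$realized_fraction,
               unname(cov[g$truth$states$state]) / 100)
})

test_that("peak generation honours degenerate preference weights", {
  ## weight 1: every peak center lies in the preferred state
  cfg <- smallConfig(preferenceWeight = 1)
  d <- generateSyntheticData(cfg)
  for (i in seq_along(d$peaks)) {
    pref <- d$truth$tfs$preferred_state[i]
    st <- assignPeakStates(d$peaks[[i]], d$seg)
    expect_true(all(st == pref))
  }
  ## nPeaks = 0: empty PeakSet, no error
  cfg0 <- smallConfig(nPeaks = 0)
  d0 <- generatePeaks(generateGenome(cfg0), cfg0)
  expect_equal(length(granges(d0$peaks[[1]])), 0L)
  ## absent preferred state errors
  cfgBad <- smallConfig(groupStates = c("I1", "E1", "E2", "E3", "ZZ"),
                        emissionPalette = rbind(defaultEmissionPalette(),
                                                ZZ = 0.5))
  expect_error(generatePeaks(generateGenome(cfgBad), cfgBad), "absent")
})

test_that("uniform peaks give occupancy enrichment consistent with 1", {
  ## preference weight 0: Monte-Carlo mean enrichment should cover 1
  devs <- replicate(5, {
    cfg <- smallConfig(seed = sample.int(1e6, 1), preferenceWeight = 0)
    d <- generateSyntheticData(cfg)
    occ <- occupancyEnrichment(d$peaks[[1]], d$seg)
    stats::weighted.mean(occ$enrichment, occ$c)  # bp-weighted mean over states
  })
  expect_lt(abs(mean(devs) - 1), 0.1)
})

test_that("expression layer plants classes exactly at zero noise", {
  cfg <- smallConfig(noiseSd = 0)
  d <- generateSyntheticData(cfg)
  m <- SummarizedExperiment::assay(d$expression)
  tr <- d$truth$genes
  ## silent genes are exactly 0 everywhere
  expect_true(all(m[tr$gene_id[tr$class == "silent"], ] == 0))
  ## planted tissue-specific genes recovered exactly
  calls <- tissueSpecificGenes(d$expression, fold = 2)
  planted <- tr$gene_id[tr$class == "tissue_specific"]
  expect_setequal(calls$gene_id, planted)
  owner <- setNames(tr$tissue, tr$gene_id)
  expect_true(all(calls$tissue == owner[calls$gene_id]))
})

test_that("co-expression ranks put functional targets under the ceiling", {
  d <- generateSyntheticData(smallConfig())
  cfg <- smallConfig()
  for (tf in names(d$truth$functionalTargets)[c(1, 5, 10)]) {
    sc <- d$coexpr[d$coexpr$tf_id == tf, ]
    ranks <- setNames(sc$score, sc$gene_id)
    fg <- d$truth$functionalTargets[[tf]]
    expect_true(all(ranks[fg] < cfg$functionalCeiling))
    expect_true(all(ranks[setdiff(names(ranks), fg)] >=
                      min(setdiff(seq_along(ranks), ranks[fg]))))
    ## every protein-coding gene gets exactly one integer rank
    expect_setequal(unname(ranks), seq_along(ranks))
    f <- coexpressionFilter(d$coexpr, tf,
                            positiveMax = cfg$functionalCeiling)
    expect_true(all(fg %in% f$positive))
  }
})

test_that("config validation rejects incoherent settings", {
  expect_error(syntheticConfig(binSize = -1), "binSize")
  expect_error(syntheticConfig(preferenceWeight = 1.5), "preferenceWeight")
  expect_error(syntheticConfig(fold = 1.5), "fold >= 2")
  expect_error(syntheticConfig(hetMix = c(H1 = 0.5, H2 = 0.2)), "hetMix")
  expect_error(syntheticConfig(groupStates = "I1"), "one state per group")
  ## infeasible packing names the remedy
  expect_error(generateGenome(syntheticConfig(nChroms = 1,
                                              chromLength = 50000,
                                              geneCount = 500)),
               "geneCount")
})
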