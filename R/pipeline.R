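#' @include synthio.R states.R domains.R expression.R compare.R tfscore.R
NULL

.pipelineDefaults <- function() {
  list(
    seed = 1,
    outdir = "chromTF_run",
    synthio = list(),
    states = list(L = 10, binwidth = 50000),
    expression = list(bins = 20, fold = 2, promoterLength = 1000),
    tfscore = list(promoterUp = 1000, promoterDown = 100,
                   maxDistance = 10000,
                   positiveMax = NULL, negativeWindow = NULL,
                   minMaxScore = 8, k = 5,
                   metric = "euclidean", linkage = "complete"))
}

.mergeConfig <- function(defaults, user, path = "", errs = new.env()) {
  if (is.null(errs$msgs)) errs$msgs <- character()
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) && path != "synthio") {
      errs$msgs <- c(errs$msgs, paste0("unknown config key: ", full))
      next
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !identical(key, "synthio"))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full,
                                      errs)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), merges it over the full default
#' parameter set, rejects unknown keys, and validates every threshold by
#' constructing the effective [syntheticConfig()].  All violations are
#' reported together.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The fully-defaulted config (class `RunConfig`).
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  config <- unclass(config)
  errs <- new.env()
  eff <- .mergeConfig(.pipelineDefaults(), config, errs = errs)
  synKeys <- names(formals(syntheticConfig))
  badSyn <- setdiff(names(eff$synthio), setdiff(synKeys, "seed"))
  if (length(badSyn))
    errs$msgs <- c(errs$msgs,
                   paste0("unknown config key: synthio.", badSyn))
  synCfg <- tryCatch(
    do.call(syntheticConfig,
            c(eff$synthio[setdiff(names(eff$synthio), badSyn)],
              list(seed = eff$seed))),
    error = function(e) { errs$msgs <- c(errs$msgs, conditionMessage(e))
                          NULL })
  with(eff$tfscore, {
    if (minMaxScore < 0)
      errs$msgs <- c(errs$msgs, "tfscore.minMaxScore must be >= 0")
    if (k < 2) errs$msgs <- c(errs$msgs, "tfscore.k must be >= 2")
  })
  if (eff$states$L < 1) errs$msgs <- c(errs$msgs, "states.L must be >= 1")
  if (eff$states$binwidth <= 0)
    errs$msgs <- c(errs$msgs, "states.binwidth must be positive")
  if (eff$expression$bins <= 0)
    errs$msgs <- c(errs$msgs, "expression.bins must be positive")
  if (length(errs$msgs))
    stop("invalid configuration:\n  ", paste(errs$msgs, collapse = "\n  "))
  if (is.null(eff$tfscore$positiveMax))
    eff$tfscore$positiveMax <- synCfg$functionalCeiling
  if (is.null(eff$tfscore$negativeWindow))
    eff$tfscore$negativeWindow <- synCfg$negativeWindow
  structure(eff, class = "RunConfig")
}

#' Dump an effective configuration as YAML
#' @param config A `RunConfig`.
#' @param path Output path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(.stripConfig(unclass(config)), path)
  invisible(path)
}

## drop non-scalar synthio entries (matrices) for YAML round-tripping
.stripConfig <- function(cfg) {
  cfg$synthio <- cfg$synthio[!vapply(cfg$synthio, is.matrix, logical(1))]
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> states -> expression -> compare -> tfscore in
#' dependency order, writing every artifact under the configured output
#' directory and returning a manifest (file, producing stage, md5).  A
#' stage failure halts downstream stages and yields a partial manifest
#' with the error recorded.  Identical config + seed gives byte-identical
#' artifacts and manifest.
#'
#' @param config A `RunConfig` from [validateConfig()] (or a list/path,
#'   validated on the fly).
#' @return Invisibly, the manifest list: `files` data.frame (path, stage,
#'   md5), `params_md5`, `error` (NULL on success).
#' @export
runPipeline <- function(config = list()) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "peaks"), showWarnings = FALSE)
  files <- data.frame(path = character(), stage = character())
  note <- function(path, stage) {
    files <<- rbind(files, data.frame(path = path, stage = stage))
  }
  failed <- NULL
  env <- new.env()

  stages <- list(
    simulate = function() {
      cfgS <- do.call(syntheticConfig,
                      c(config$synthio[!vapply(config$synthio, is.null,
                                               logical(1))],
                        list(seed = config$seed)))
      env$cfgS <- cfgS
      env$data <- generateSyntheticData(cfgS)
      d <- env$data
      writeSegmentation(d$seg, file.path(out, "segmentation.bed"))
      note("segmentation.bed", "simulate")
      utils::write.table(data.frame(names(chromSizes(d$seg)),
                                    unname(chromSizes(d$seg))),
                         file.path(out, "chrom.sizes"), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      note("chrom.sizes", "simulate")
      writeGeneModels(d$genes, file.path(out, "genes.gff3"))
      note("genes.gff3", "simulate")
      writeEmissions(d$emissions, file.path(out, "emissions.tsv"))
      note("emissions.tsv", "simulate")
      writeExpression(d$expression, file.path(out, "expression.tsv"))
      note("expression.tsv", "simulate")
      writeCoexpression(d$coexpr, file.path(out, "coexpression.tsv"))
      note("coexpression.tsv", "simulate")
      for (tf in names(d$peaks)) {
        writePeaks(d$peaks[[tf]],
                   file.path(out, "peaks", paste0(tf, ".narrowPeak")))
        note(file.path("peaks", paste0(tf, ".narrowPeak")), "simulate")
      }
      writeTruth(d$truth, file.path(out, "truth.json"))
      note("truth.json", "simulate")
    },
    states = function() {
      cs <- readChromSizes(file.path(out, "chrom.sizes"))
      env$seg <- readSegmentation(file.path(out, "segmentation.bed"),
                                  chromSizes = cs,
                                  binSize = env$cfgS$binSize)
      env$genes <- readGeneModels(file.path(out, "genes.gff3"))
      env$pc <- subsetGenes(env$genes,
                            featureClass(env$genes) == "protein_coding")
      cov <- genomeCoverage(env$seg)
      writeTable(data.frame(state = names(cov), percent = unname(cov)),
                 file.path(out, "coverage.tsv"))
      note("coverage.tsv", "states")
      comp <- featureComposition(env$seg, env$genes)
      writeTable(comp, file.path(out, "composition.tsv"))
      note("composition.tsv", "states")
      env$nb <- neighbourhoodEnrichment(env$seg, env$pc,
                                        L = config$states$L)
      writeTable(env$nb$enrichment, file.path(out, "neighbourhood.tsv"))
      note("neighbourhood.tsv", "states")
      em <- readEmissions(file.path(out, "emissions.tsv"))
      env$domains <- assignNomenclature(
        classifyDomains(em, comp), env$nb, env$seg)
      writeTable(env$domains, file.path(out, "domains.tsv"))
      note("domains.tsv", "states")
      writeTable(chromosomalDistribution(env$seg,
                                         binwidth = config$states$binwidth),
                 file.path(out, "chromdist.tsv"))
      note("chromdist.tsv", "states")
    },
    expression = function() {
      env$expr <- readExpression(file.path(out, "expression.tsv"))
      cv <- computeCV(env$expr)
      writeTable(data.frame(gene_id = names(cv), cv = unname(cv)),
                 file.path(out, "cv.tsv"))
      note("cv.tsv", "expression")
      ref <- paste0("tissue", 1L)
      m <- .tpmMatrix(env$expr)
      tis <- .tissueTags(env$expr)
      refTpm <- rowMeans(m[, tis == ref, drop = FALSE])
      refTpm <- refTpm[intersect(names(refTpm), geneIds(env$pc))]
      env$bins <- binGenes(refTpm, B = config$expression$bins)
      writeTable(data.frame(gene_id = names(env$bins),
                            bin = unname(env$bins)),
                 file.path(out, "tpm_bins.tsv"))
      note("tpm_bins.tsv", "expression")
      prom <- promoterRegions(env$pc,
                              length = config$expression$promoterLength,
                              chromSizes = chromSizes(env$seg))
      writeTable(stateProportionProfile(prom, env$bins, env$seg),
                 file.path(out, "promoter_profile.tsv"))
      note("promoter_profile.tsv", "expression")
      env$bodyProfile <- stateProportionProfile(geneBodyRegions(env$pc),
                                                env$bins, env$seg)
      writeTable(env$bodyProfile, file.path(out, "body_profile.tsv"))
      note("body_profile.tsv", "expression")
      writeTable(tissueSpecificGenes(env$expr,
                                     fold = config$expression$fold),
                 file.path(out, "tissue_specific.tsv"))
      note("tissue_specific.tsv", "expression")
    },
    compare = function() {
      map <- stats::setNames(env$domains$domain, env$domains$state)
      domSeg <- renameStates(env$seg, map)
      tm <- transitionMatrix(env$seg, domSeg)
      writeTable(tm, file.path(out, "transitions.tsv"))
      note("transitions.tsv", "compare")
      long <- data.frame(stateA = rep(rownames(tm), ncol(tm)),
                         stateB = rep(colnames(tm), each = nrow(tm)),
                         bp = as.vector(tm))
      writeTable(long[long$bp > 0, ], file.path(out, "alluvial.tsv"))
      note("alluvial.tsv", "compare")
      writeTable(stateJaccard(env$seg, domSeg),
                 file.path(out, "jaccard.tsv"))
      note("jaccard.tsv", "compare")
    },
    tfscore = function() {
      coex <- readCoexpression(file.path(out, "coexpression.tsv"))
      universe <- geneIds(env$pc)
      tfc <- config$tfscore
      peakFiles <- list.files(file.path(out, "peaks"), full.names = TRUE)
      occ <- list(); act <- list(); env$peaks <- list()
      for (f in sort(peakFiles)) {
        ps <- readPeaks(f, assay = "chip", chromSizes = chromSizes(env$seg))
        env$peaks[[tfId(ps)]] <- ps
        occ[[tfId(ps)]] <- occupancyEnrichment(ps, env$seg)
        tg <- annotateTargets(ps, env$pc, env$seg,
                              promoterWindow = c(tfc$promoterUp,
                                                 tfc$promoterDown),
                              maxDistance = tfc$maxDistance)
        cf <- coexpressionFilter(coex, tfId(ps),
                                 positiveMax = tfc$positiveMax,
                                 negativeWindow = tfc$negativeWindow)
        act[[tfId(ps)]] <- activityScore(tg$targetsByState,
                                         c(cf$positive, cf$negative),
                                         universe, tf = tfId(ps))
      }
      writeTable(do.call(rbind, occ), file.path(out, "occupancy.tsv"))
      note("occupancy.tsv", "tfscore")
      env$activity <- do.call(rbind, act)
      rownames(env$activity) <- NULL
      writeTable(env$activity, file.path(out, "activity.tsv"))
      note("activity.tsv", "tfscore")
      env$scores <- buildScoreMatrix(env$activity,
                                     minMaxScore = tfc$minMaxScore)
      writeTable(env$scores$matrix, file.path(out, "score_matrix.tsv"))
      note("score_matrix.tsv", "tfscore")
      env$clust <- clusterTFs(env$scores$matrix, k = tfc$k,
                              metric = tfc$metric, linkage = tfc$linkage)
      writeTable(data.frame(tf_id = names(env$clust$clusters),
                            cluster = unname(env$clust$clusters)),
                 file.path(out, "clusters.tsv"))
      note("clusters.tsv", "tfscore")
      truth <- jsonlite::read_json(file.path(out, "truth.json"),
                                   simplifyVector = TRUE)
      fam <- stats::setNames(paste0("family", truth$tfs$group),
                             truth$tfs$tf_id)
      writeTable(familyEnrichment(env$clust$clusters, fam),
                 file.path(out, "families.tsv"))
      note("families.tsv", "tfscore")
      byCl <- split(names(env$clust$clusters), env$clust$clusters)
      hist <- tssBindingHistogram(lapply(byCl, function(tfs)
        env$peaks[tfs]), env$pc)
      writeTable(hist, file.path(out, "tss_histogram.tsv"))
      note("tss_histogram.tsv", "tfscore")
    })

  for (nm in names(stages)) {
    res <- tryCatch({ stages[[nm]](); NULL },
                    error = function(e)
                      paste0("stage '", nm, "': ", conditionMessage(e)))
    if (!is.null(res)) { failed <- res; break }
  }
  files$md5 <- unname(tools::md5sum(file.path(out, files$path)))
  paramsFile <- file.path(out, "effective_config.yaml")
  writeConfig(config, paramsFile)
  manifest <- list(files = files,
                   params_md5 = unname(tools::md5sum(paramsFile)),
                   error = failed)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(failed)) warning(failed)
  invisible(manifest)
}

#' Subset a GeneModelSet
#' @param genes A [GeneModelSet].
#' @param keep Logical or integer index over genes.
#' @return A [GeneModelSet] with the selected genes.
#' @export
subsetGenes <- function(genes, keep) GeneModelSet(genes@ranges[keep])
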