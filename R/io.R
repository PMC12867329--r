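#' @include methods.R
NULL

.skipLines <- function(lines) {
  grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
}

.splitFields <- function(lines) strsplit(lines, "\t| +")

#' Read a ChromHMM-style segmentation BED
#'
#' Accepts both the "dense" and the "segments" BED dialects (only the first
#' four columns are used; column 4 is the state label).  Coordinates are
#' BED 0-based half-open and are converted exactly to the internal GRanges
#' representation.  Gaps between records (unmappable bins ChromHMM may
#' omit) are tolerated: they are filled with the reserved label
#' `"unassigned"` and reported via a warning; overlapping records are an
#' error naming the first collision.
#'
#' @param path BED file (4+ columns).
#' @param chromSizes Optional named vector of chromosome lengths; records on
#'   chromosomes absent from it are an error, and coverage is completed to
#'   `[0, size)` per chromosome.
#' @param binSize Segmentation grid in bp (default 200).
#' @param stateLevels Optional ordered state labels.
#' @return A [StateSegmentation].
#' @export
readSegmentation <- function(path, chromSizes = NULL, binSize = 200,
                             stateLevels = NULL) {
  lines <- readLines(path)
  keep <- !.skipLines(lines)
  fields <- .splitFields(lines[keep])
  lineno <- which(keep)
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad))
    stop("malformed BED row at line ", lineno[bad[1]], " of ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  state <- vapply(fields, `[[`, "", 4L)
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1]
    stop("malformed coordinates at line ", lineno[bad], " of ", path)
  }
  if (!is.null(chromSizes)) {
    unknown <- setdiff(unique(chrom), names(chromSizes))
    if (length(unknown))
      stop("unknown chromosome(s) in segmentation: ",
           paste(unknown, collapse = ", "))
  } else {
    sz <- tapply(end0, chrom, max)
    chromSizes <- stats::setNames(as.numeric(sz), names(sz))
  }
  df <- data.frame(chrom, start0, end0, state)
  df <- df[order(df$chrom, df$start0), ]
  filled <- list()
  gapBp <- 0
  for (c in names(chromSizes)) {
    d <- df[df$chrom == c, ]
    n <- nrow(d)
    if (n > 1L) {
      ov <- which(d$start0[-1] < d$end0[-n])
      if (length(ov)) {
        i <- ov[1]
        stop(sprintf("overlapping segmentation records on %s: [%d,%d) and [%d,%d)",
                     c, d$start0[i], d$end0[i], d$start0[i + 1], d$end0[i + 1]))
      }
    }
    bounds <- c(0, if (n) as.vector(rbind(d$start0, d$end0)), chromSizes[[c]])
    gs <- bounds[seq(1, length(bounds), by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)]
    gap <- ge > gs
    if (any(gap)) {
      filled[[c]] <- data.frame(chrom = c, start0 = gs[gap], end0 = ge[gap],
                                state = UNASSIGNED)
      gapBp <- gapBp + sum(ge[gap] - gs[gap])
    }
  }
  if (gapBp > 0) {
    warning("filled ", gapBp, " bp of segmentation gaps with '",
            UNASSIGNED, "'")
    df <- rbind(df, do.call(rbind, filled))
  }
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1L, df$end0), state = df$state)
  StateSegmentation(gr, states = stateLevels, chromSizes = chromSizes,
                    binSize = binSize)
}

#' Write a segmentation as a 4-column BED
#'
#' Unassigned gap-filler intervals are dropped on write; a subsequent
#' [readSegmentation()] refills them, making write-then-read the identity
#' on the canonical form.
#'
#' @param seg A [StateSegmentation].
#' @param path Output path.
#' @export
writeSegmentation <- function(seg, path) {
  gr <- seg@ranges[seg@ranges$state != UNASSIGNED]
  df <- data.frame(as.character(seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr), gr$state)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps gene-level records only (`gene`, `transposable_element*`,
#' `pseudogene`, `*_gene` types), converts the 1-based inclusive GFF
#' coordinates exactly, derives TSS/TTS strand-aware and infers the feature
#' class: types starting `transposable_element` map to `TE`, type `gene` to
#' `protein_coding`, anything else to `other`.  Records without strand are
#' skipped with a warning.
#'
#' @param path GFF3 file.
#' @return A [GeneModelSet].
#' @importFrom rtracklayer import export
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type == "gene" | grepl("^transposable_element", type) |
    grepl("gene$", type)
  gr <- gr[keep]
  type <- type[keep]
  nostrand <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(nostrand)) {
    warning("skipped ", sum(nostrand), " gene record(s) without strand")
    gr <- gr[!nostrand]
    type <- type[!nostrand]
  }
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  if (is.null(id)) id <- paste0("gene_", seq_along(gr))
  id[is.na(id)] <- paste0("gene_", which(is.na(id)))
  fc <- ifelse(grepl("^transposable_element", type), "TE",
               ifelse(type == "gene", "protein_coding", "other"))
  out <- granges(gr)
  mcols(out) <- NULL
  out$gene_id <- as.character(id)
  out$feature_class <- fc
  GeneModelSet(out)
}

#' Write gene models as GFF3
#'
#' Inverse of [readGeneModels()]: `TE` genes are written with type
#' `transposable_element_gene`, protein-coding with `gene`, others with
#' `ncRNA_gene`, so the class survives a round trip.
#'
#' @param genes A [GeneModelSet].
#' @param path Output path.
#' @export
writeGeneModels <- function(genes, path) {
  gr <- genes@ranges
  out <- granges(gr)
  out$source <- "chromTF"
  out$type <- ifelse(gr$feature_class == "TE", "transposable_element_gene",
                     ifelse(gr$feature_class == "protein_coding", "gene",
                            "ncRNA_gene"))
  out$ID <- gr$gene_id
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read TF peaks from narrowPeak or BED
#'
#' 10-column files are treated as ENCODE narrowPeak (summit offset in
#' column 10, with the `-1` sentinel meaning "absent"); 3- to 6-column
#' files as plain BED.  Malformed rows raise an error with their line
#' number.
#'
#' @param path Peak file.
#' @param tfId TF/experiment identifier (defaults to the file base name).
#' @param assay `"chip"`, `"dap"` or `"pwm"`.
#' @param chromSizes Optional named sizes; peaks outside them are an error.
#' @return A [PeakSet].
#' @export
readPeaks <- function(path, tfId = sub("\\.[^.]*$", "", basename(path)),
                      assay = "chip", chromSizes = NULL) {
  lines <- readLines(path)
  keep <- !.skipLines(lines)
  fields <- .splitFields(lines[keep])
  lineno <- which(keep)
  nfield <- vapply(fields, length, 1L)
  if (length(nfield) && length(unique(nfield)) > 1L)
    stop("ragged peak file ", path, ": first irregular row at line ",
         lineno[which(nfield != nfield[1])[1]])
  if (length(nfield) && nfield[1] < 3L)
    stop("malformed peak row at line ", lineno[1], " of ", path)
  if (length(fields) == 0L) {
    return(PeakSet(tfId, assay, GRanges()))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0) || any(start0 >= end0)) {
    bad <- which(is.na(start0) | is.na(end0) | start0 >= end0)[1]
    stop("malformed peak coordinates at line ", lineno[bad], " of ", path)
  }
  if (!is.null(chromSizes)) {
    unknown <- setdiff(unique(chrom), names(chromSizes))
    if (length(unknown))
      stop("peaks on unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(end0 > chromSizes[chrom]))
      stop("peak beyond chromosome end at line ",
           lineno[which(end0 > chromSizes[chrom])[1]], " of ", path)
  }
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (nfield[1] >= 5L)
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (nfield[1] >= 10L) {
    summit <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 10L)))
    summit[!is.na(summit) & summit < 0] <- NA  # -1 sentinel: absent
    gr$summit <- summit
  }
  PeakSet(tfId, assay, gr)
}

#' Write a PeakSet as narrowPeak
#' @param peaks A [PeakSet].
#' @param path Output path.
#' @export
writePeaks <- function(peaks, path) {
  gr <- peaks@ranges
  score <- if (is.null(gr$score)) rep(0, length(gr)) else gr$score
  summit <- if (is.null(gr$summit)) rep(NA_real_, length(gr)) else gr$summit
  summit[is.na(summit)] <- -1
  df <- data.frame(as.character(seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   paste0(peaks@tfId, "_peak", seq_along(gr)),
                   score, ".", 0, -1, -1, summit)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TPM expression matrix
#'
#' TSV with a header row; first column gene ids, remaining columns samples.
#' Tissue tags default to the sample name with a trailing `_<replicate>`
#' suffix removed.  Duplicate gene ids and negative values are errors.
#'
#' @param path TSV file.
#' @param tissues Optional character vector of tissue tags per sample.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"tpm"` and a `tissue` column in `colData`.
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @export
readExpression <- function(path, tissues = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate gene id in ", path, ": ",
         df[[1]][duplicated(df[[1]])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative TPM values in ", path)
  makeExpression(m, tissues)
}

#' Assemble an expression SummarizedExperiment from a TPM matrix
#' @param m Genes-by-samples TPM matrix with dimnames.
#' @param tissues Tissue tag per sample; default strips a `_<rep>` suffix
#'   from the sample names.
#' @return SummarizedExperiment with assay `tpm`.
#' @export
makeExpression <- function(m, tissues = NULL) {
  if (is.null(tissues)) tissues <- sub("_[^_]*$", "", colnames(m))
  stopifnot(length(tissues) == ncol(m))
  SummarizedExperiment(assays = list(tpm = m),
                       colData = S4Vectors::DataFrame(
                         tissue = tissues, row.names = colnames(m)))
}

#' Write an expression matrix as TSV
#' @param expr SummarizedExperiment (assay `tpm`) or matrix.
#' @param path Output path.
#' @export
writeExpression <- function(expr, path) {
  m <- .tpmMatrix(expr)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tpmMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) SummarizedExperiment::assay(expr, "tpm")
  else as.matrix(expr)
}

.tissueTags <- function(expr) {
  if (is(expr, "SummarizedExperiment"))
    as.character(SummarizedExperiment::colData(expr)$tissue)
  else sub("_[^_]*$", "", colnames(expr))
}

#' Read an ATTED-style co-expression table
#'
#' TSV with header `tf_id`, `gene_id`, `score`; lower scores mean stronger
#' positive co-expression.  One row per (TF, gene); duplicates and negative
#' scores are errors.
#'
#' @param path TSV file.
#' @return data.frame with columns `tf_id`, `gene_id`, `score`.
#' @export
readCoexpression <- function(path) {
  df <- utils::read.delim(path)
  need <- c("tf_id", "gene_id", "score")
  if (!all(need %in% names(df)))
    stop("co-expression table must have columns ", paste(need, collapse = ", "))
  dup <- duplicated(df[c("tf_id", "gene_id")])
  if (any(dup))
    stop("duplicate (tf_id, gene_id) pair at data row ", which(dup)[1])
  if (any(df$score < 0)) stop("co-expression scores must be >= 0")
  df[need]
}

#' Write a co-expression table
#' @param coexpr data.frame `tf_id`, `gene_id`, `score`.
#' @param path Output path.
#' @export
writeCoexpression <- function(coexpr, path) {
  utils::write.table(coexpr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ChromHMM emissions table
#'
#' TSV, states as rows (first column), marks as columns.
#' @param path TSV file.
#' @return An [EmissionMatrix].
#' @export
readEmissions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  EmissionMatrix(m)
}

#' Write an emissions table
#' @param em An [EmissionMatrix].
#' @param path Output path.
#' @export
writeEmissions <- function(em, path) {
  df <- data.frame(state = rownames(em@p), em@p, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path TSV: chromosome, length.
#' @return Named numeric vector.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, col.names = c("chrom", "size"))
  stats::setNames(as.numeric(df$size), as.character(df$chrom))
}

#' Read a bedGraph signal track
#' @param path bedGraph file.
#' @return GRanges with a `score` column.
#' @export
readBedGraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a data frame or matrix as a deterministic TSV
#'
#' Matrices are written with an explicit `id` first column holding the row
#' names, so write-then-read restores the canonical form.
#'
#' @param obj data.frame or matrix.
#' @param path Output path.
#' @export
writeTable <- function(obj, path) {
  if (is.matrix(obj))
    obj <- data.frame(id = rownames(obj), obj, check.names = FALSE)
  utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
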