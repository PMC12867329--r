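#' @include states.R
NULL

.HET_MARK_RE <- "H3K9me[12]|H3K27me1|H2A\\.?W|H2A\\.?M"
.FAC_MARK_RE <- "H3K27me3"
.FAC_PAIR_RE <- c("H2A\\.?Z", "H2A(K[0-9]+)?ub")

#' Classify chromatin states into major domains
#'
#' Assigns each state to one of the four chromatin domains by an explicit,
#' ordered rule cascade:
#' \enumerate{
#'   \item \strong{H} (constitutive heterochromatin) if the maximum
#'     emission over heterochromatin marks (H3K9me1/2, H3K27me1,
#'     H2A.W/H2A.M by default) is at least `tauH` \emph{and} the TE bp
#'     proportion is at least `tauTE`;
#'   \item \strong{I} (intergenic / nucleosome-free) if the maximum
#'     emission over \emph{all} marks is below `tauI`;
#'   \item \strong{F} (facultative heterochromatin) if the facultative
#'     signal — the larger of the H3K27me3 emission and the joint
#'     H2A.Z + H2Aub emission (the minimum of the two, since H2A.Z alone
#'     also marks the +1 nucleosome of active genes) — is at least `tauF`;
#'   \item \strong{E} (euchromatin) otherwise.
#' }
#' Every assignment records which rule fired.
#'
#' @param emissions An [EmissionMatrix].
#' @param composition State-by-feature matrix from [featureComposition()]
#'   (the `TE` column is used).
#' @param neighbourhood Optional `NeighbourhoodMatrix`; carried through to
#'   [assignNomenclature()], not used by the rules.
#' @param accessibility Reserved for an accessibility-based refinement;
#'   currently unused.
#' @param tauH,tauTE,tauI,tauF Rule thresholds (defaults 0.5, 0.3, 0.2,
#'   0.5).
#' @param hetMarks,facMarks Regular expressions (or explicit mark vectors)
#'   selecting the heterochromatin / solo facultative mark columns.
#' @param facPairMarks Length-2 list/vector of regular expressions for the
#'   paired facultative marks (default H2A.Z and H2Aub).
#' @return data.frame `state`, `domain` (H/F/E/I), `rule` (the fired rule).
#' @export
classifyDomains <- function(emissions, composition, neighbourhood = NULL,
                            accessibility = NULL,
                            tauH = 0.5, tauTE = 0.3, tauI = 0.2, tauF = 0.5,
                            hetMarks = .HET_MARK_RE,
                            facMarks = .FAC_MARK_RE,
                            facPairMarks = .FAC_PAIR_RE) {
  p <- emissions@p
  st <- rownames(p)
  if (!all(st %in% rownames(composition)))
    stop("composition is missing states: ",
         paste(setdiff(st, rownames(composition)), collapse = ", "))
  pick <- function(spec) {
    if (length(spec) == 1L && !spec %in% colnames(p))
      grep(spec, colnames(p), value = TRUE)
    else intersect(spec, colnames(p))
  }
  het <- pick(hetMarks)
  fac <- pick(facMarks)
  pair <- lapply(facPairMarks, pick)
  if (length(het) == 0L && length(fac) == 0L &&
      any(lengths(pair) == 0L))
    stop("emission matrix has none of the rule marks; need marks matching ",
         hetMarks, " or ", facMarks, " or both of ",
         paste(unlist(facPairMarks), collapse = " + "))
  maxOr0 <- function(v) if (length(v)) max(v) else 0
  res <- lapply(st, function(s) {
    eh <- maxOr0(p[s, het])
    efSolo <- maxOr0(p[s, fac])
    efPair <- if (all(lengths(pair) > 0))
      min(vapply(pair, function(mk) max(p[s, mk]), numeric(1))) else 0
    ef <- max(efSolo, efPair)
    ea <- max(p[s, ])
    te <- composition[s, "TE"]
    if (eh >= tauH && te >= tauTE)
      c("H", sprintf("het emission %.2f >= %.2f & TE %.2f >= %.2f",
                     eh, tauH, te, tauTE))
    else if (ea < tauI)
      c("I", sprintf("max emission %.2f < %.2f", ea, tauI))
    else if (ef >= tauF)
      c("F", sprintf("facultative emission %.2f >= %.2f", ef, tauF))
    else
      c("E", "default (euchromatin)")
  })
  data.frame(state = st,
             domain = vapply(res, `[[`, "", 1L),
             rule = vapply(res, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

## Weighted median helper (bp-weighted).
.weightedMedian <- function(x, w) .weightedQuantile(x, w, 0.5)

#' Assign the field's state nomenclature
#'
#' Numbers states within each domain and prefixes the domain letter
#' (optionally with a species prefix, e.g. `Mp`).  Euchromatin, facultative
#' and intergenic states are numbered by the offset of their peak TSS
#' neighbourhood enrichment, ascending from the TSS into the gene body.
#' Ties are broken by the centroid of the enrichment profile, then by
#' original label.  Heterochromatin states are numbered by their bp-weighted
#' median distance to the centromere (ascending) when centromere
#' coordinates are supplied, otherwise by genome coverage (descending).
#'
#' @param domains data.frame from [classifyDomains()].
#' @param neighbourhood `NeighbourhoodMatrix` from
#'   [neighbourhoodEnrichment()] with TSS anchors.
#' @param seg The [StateSegmentation] (for coverage / centromere distance).
#' @param centromeres Optional named vector chromosome -> centromere bp.
#' @param prefix Optional species prefix prepended to every name.
#' @return The `domains` data.frame with added columns `name` and
#'   `order_key`.
#' @export
assignNomenclature <- function(domains, neighbourhood, seg,
                               centromeres = NULL, prefix = "") {
  enr <- neighbourhood$enrichment
  offs <- as.numeric(colnames(enr))
  cov <- genomeCoverage(seg)
  gr <- seg@ranges
  keyFor <- function(s, dom) {
    if (dom == "H") {
      if (!is.null(centromeres)) {
        sgr <- gr[gr$state == s]
        mid <- (GenomicRanges::start(sgr) - 1 + GenomicRanges::end(sgr)) / 2
        d <- abs(mid - centromeres[as.character(seqnames(sgr))])
        c(.weightedMedian(d, GenomicRanges::width(sgr)), 0)
      } else c(-cov[[s]], 0)
    } else {
      e <- enr[s, ]
      if (all(!is.finite(e)) || sum(e, na.rm = TRUE) == 0)
        return(c(Inf, Inf))
      am <- offs[which.max(e)]
      centroid <- sum(offs * e, na.rm = TRUE) / sum(e, na.rm = TRUE)
      c(am, centroid)
    }
  }
  domains$name <- NA_character_
  domains$order_key <- NA_real_
  for (dom in unique(domains$domain)) {
    idx <- which(domains$domain == dom)
    keys <- t(vapply(domains$state[idx], keyFor, numeric(2), dom = dom))
    o <- order(keys[, 1], keys[, 2], domains$state[idx])
    domains$name[idx[o]] <- paste0(prefix, dom, seq_along(idx))
    domains$order_key[idx] <- keys[, 1]
  }
  domains
}

#' Relabel a segmentation's states
#'
#' @param seg A [StateSegmentation].
#' @param map Named character vector old label -> new label (e.g. built
#'   from [assignNomenclature()] output as `setNames(name, state)`).
#' @return A relabelled [StateSegmentation]; new state order follows the
#'   sorted new names.
#' @export
renameStates <- function(seg, map) {
  missing <- setdiff(seg@states, names(map))
  if (length(missing))
    stop("map is missing states: ", paste(missing, collapse = ", "))
  gr <- seg@ranges
  keep <- gr$state != UNASSIGNED
  gr$state[keep] <- unname(map[gr$state[keep]])
  StateSegmentation(gr, states = sort(unique(unname(map))),
                    chromSizes = seg@chromSizes, binSize = seg@binSize)
}
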