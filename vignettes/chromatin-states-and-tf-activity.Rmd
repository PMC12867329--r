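---
title: "Chromatin states and transcription-factor activity: methods"
author: "chromTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin states and transcription-factor activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromTF)
```

# Scope

chromTF provides the downstream analytics that follow a multivariate-HMM
chromatin-state segmentation of a plant genome: per-state genome
statistics, domain classification and nomenclature, positional enrichment
around gene anchors, the association of states with transcription, the
comparison of two state models, and a transcription-factor (TF)
occupancy/activity scoring framework. Segmentation *training* is out of
scope: segmentations (BED) and emission tables are consumed as inputs, on
their native 200 bp bin grid.

Because the genome-scale inputs behind such analyses are large and
heterogeneous, the package ships a synthetic-epigenome generator with
planted ground truth. Every analytical claim the package makes is
exercised against either an exact brute-force oracle or a planted truth,
at desk scale.

# Data model

All coordinates live in `GRanges` (1-based, closed), the standard
container of this ecosystem; BED and bedGraph inputs (0-based half-open)
and GFF3 inputs (1-based closed) are converted exactly at the I/O
boundary. Two pieces of arithmetic are deliberately done on the 0-based
half-open scale because they are defined there:

* the **peak center** of `[start0, end0)` is `floor((start0 + end0)/2)`;
* the **bin** containing a 0-based position `p` is `p %/% binSize`.

A `StateSegmentation` must tile every chromosome completely; gaps in the
input BED (bins the segmenter left uncalled, e.g. unmappable regions) are
filled with the reserved label `"unassigned"` at read time and excluded
from every denominator. Both the ChromHMM "dense" and "segments" BED
dialects are accepted — only the first four columns are read, so the
dialect needs no flag beyond documentation.

For gene models the TSS is the interval start for `+` genes and the
interval end for `-` genes. Since the `-` strand TSS is an *exclusive*
boundary, the anchor bin used by the neighbourhood analysis is the bin
containing the first transcribed base (`tss - 1` for `-` genes). This
keeps offset 0 on the gene for both strands and makes `+`/`-` genes
exactly symmetric; the alternative (literally binning the boundary
coordinate) shifts every `-` gene's profile by one bin whenever the TSS
falls on a bin boundary.

# Per-state statistics

**Genome coverage** is `100 * bp(state) / assigned bp`. Using assigned
rather than total bp keeps the percentages summing to 100 on partially
covered inputs; `denominator = "genome"` restores the naive definition.

**Feature composition** distributes each state's bp over
protein-coding genes, transposable elements, other annotated features and
intergenic space. Overlapping annotations are resolved by the fixed
priority protein_coding > TE > other, so the per-state proportions always
sum to 1.

**Neighbourhood enrichment** around TSS/TTS anchors follows the
segmentation's own bin grid (no re-binning): for state $s$ at signed bin
offset $k$,

$$\mathrm{enr}(s,k) =
  \frac{\#\{\text{anchors with state } s \text{ at offset } k\}/n_k}
       {\text{genome fraction of } s},$$

with offsets mirrored for `-` strand anchors so positive offsets always
point into the gene body. Anchors whose offset bin leaves the chromosome
or lands on an unassigned bin are dropped from that offset's denominator
$n_k$. At any offset where nothing was dropped,
$\sum_s f(s)\,\mathrm{enr}(s,k) = 1$ exactly (law of total probability) —
a conservation law the test suite asserts. The background is the uniform
genome fraction; a signal-based background is a conceivable refinement
and the argument slot for it is reserved.

The default half-window is `L = 10` bins (±2 kb at 200 bp), wide enough
to span a promoter and the first nucleosomes of a plant gene.

# Domain classification and nomenclature

States are classified into the four canonical chromatin domains by an
ordered, logged rule cascade with explicit thresholds (the published
practice is classification by expert inspection; explicit thresholds make
it testable and auditable):

1. **H** — constitutive heterochromatin: max emission over
   heterochromatin marks (H3K9me1/2, H3K27me1, H2A.W/H2A.M) ≥ 0.5
   *and* TE bp proportion ≥ 0.3. The TE condition prevents
   H3K27me1-carrying gene-body states from being swallowed.
2. **I** — intergenic/NFR: max emission over *all* marks < 0.2.
3. **F** — facultative heterochromatin: facultative signal ≥ 0.5, where
   the signal is the larger of the H3K27me3 emission and
   `min(H2A.Z, H2Aub)`. The minimum encodes that H2A.Z alone also marks
   the +1 nucleosome of active genes and must not trigger F on its own.
4. **E** — euchromatin otherwise.

All four thresholds and the three mark sets are arguments; every
assignment records the rule that fired.

Nomenclature then numbers states within each domain: E/F/I states by the
offset of their peak TSS enrichment, ascending from the TSS into the gene
body (ties broken by the centroid of the profile, then by original
label); H states by their bp-weighted median distance to the centromere
when centromere coordinates are given, otherwise by genome coverage
descending.

# Expression association

The coefficient of variation uses the sample (n−1) standard deviation —
the conventional estimator; genes with zero mean are excluded (logged)
since their CV is undefined. Gene bins are rank-based with sizes
differing by at most one, ties broken by gene id so the binning is
reproducible. TPM ordering uses a designated reference tissue rather than
the row mean, matching the practice of ranking by expression in the
tissue the chromatin data came from. Promoters are the 1,000 bp upstream
of the TSS, strand-aware and clipped at chromosome edges; gene-body
profiles reuse the same proportion machinery with the gene interval as
the region. Bin profiles pool bp across member genes (state bp / assigned
bp), so rows sum to 1.

A gene is called tissue-specific when its mean TPM in some tissue is at
least two-fold its mean across tissues. Genes qualifying in several
tissues are all reported with a multiplicity flag, since dropping or
keeping them is a downstream choice; genes with zero overall mean are
never called (the rule would otherwise degenerate at 0 ≥ 0).

# Model comparison

Transition matrices and per-state Jaccard indices are computed at bp
resolution (bin-exact anyway when both maps share the grid), excluding
unassigned bp of either map. The mark-removal experiment reports, per
reduced model, each full-model state's best-match Jaccard, optionally
aggregated per domain — quantifying which domains a mark set is needed to
define. Cross-species emission clustering merges two emission matrices on
a user-supplied mark map (e.g. one species' H2A.W equated with the
other's H2A.M.2) and emits a language-neutral merge table alongside the
`hclust` object.

Experimentally determined TSS/TTS anchors update gene coordinates by
nearest same-strand assignment within 500 bp by default (the matched
genes are stranded protein-coding genes, so strand agreement is
required); equidistant candidates go to the smaller gene id, and shifts
are reported in gene orientation (positive = downstream).

# TF occupancy and activity

Occupancy enrichment for TF peaks in state $s$ is the bp-level ratio
$(a_s/b)/(c_s/d)$ — peak bp in $s$ over total peak bp, against state bp
over assigned bp. Peaks are merged first so overlapping peaks do not
double-count bases; a peak set tiling the whole genome scores exactly 1
in every state.

Activity scoring proceeds per TF: each peak is assigned the state of its
center bin and a target gene via a promoter (−1000..+100 bp around the
TSS) → gene-body → nearest-TSS (≤ 10 kb) cascade. The TF's co-expressed
genes are the union of the positive tail (rank < 2000 by default) and the
negative tail (rank > per-TF max − 1000) of an ATTED-style rank table.
For each state, a one-sided (greater) Fisher exact test asks whether the
state's targets are enriched for co-expressed genes against the
whole-genome universe of $N$ genes, using the margins-derived 2×2 table
$(k,\; m-k;\; q-k,\; N-m-q+k)$. The four counts sometimes printed as a
2×2 "data" matrix (overlap, targets; co-expressed, $N$) double-count the
overlap and are not a valid contingency table; the margins-derived table
is the statistically coherent reading, and the literal layout remains
available behind `tableConvention = "literal"` for comparison. The
p-value is computed by the hypergeometric tail (`phyper`), which the test
suite pins against both `fisher.test` and an independent closed-form
enumeration. The null uses the full deterministic genome counts rather
than an actually resampled gene set: the resampling reading of "a random
sample of genes" converges to exactly this test and adds variance without
information.

The activity score is
$-\log_{10}(p) + \log_2(\mathrm{OR} + 1)$, with the sample odds ratio
given a Haldane 0.5 correction on zero cells so the score stays finite
(the estimator is otherwise unspecified; the conditional-MLE OR from
`fisher.test` differs only in degenerate tables). States without targets
score exactly 0 ($p=1$, OR defined as 0). TFs whose maximum raw score is
strictly below 8 are discarded as low-confidence; the surviving rows are
divided by their own maximum, so every retained TF peaks at 1.

TF clustering uses Euclidean distance with complete linkage by default
(the common default of the heatmap tooling used in this field), cut at a
user-chosen $k$ — no selection rule for $k$ is imposed. Family enrichment
across clusters reuses the same exact test with Benjamini–Hochberg
q-values. Positive and negative co-expression are pooled into a single
co-expressed set for the test (mirroring the single filtered list the
procedure describes); per-sign testing is a one-line variation left to
the caller by filtering the sets.

# The synthetic epigenome

The generator plants every signal the analyses are meant to detect, and
its defaults are the study conditions used by the test suite:

* **Genome**: 2 chromosomes × 500 kb, 200 bp bins. Each chromosome has a
  central TE compartment (10%) split 65/35 between two H states, the
  inner one centred on the (synthetic) centromere — giving the
  centromere-distance nomenclature something to order. TE gene records
  cover the compartment.
* **Genes**: 500, placed on equally wide slots on both arms; footprint =
  2 promoter bins + 5 body bins. Footprint bins are labelled by sampling
  per-offset categorical state distributions: promoter bins are the NFR
  state I1; the TSS bin mixes I1/E1; E1–E4 grade into the body with
  planted modes +1..+4. Body bins are swapped for the facultative state
  F1 with probability $(1-\text{rank percentile of baseline TPM})^2$,
  planting a smooth repression gradient: silent genes are nearly all F1,
  the median gene ~25%. Remaining bins take a featureless filler state.
* **Expression**: 5 tissues × 2 replicates; log-normal baselines
  (meanlog 2, sdlog 1.5 — a heavy-tailed TPM distribution), 20% silent
  genes at exactly 0, 20% tissue-specific genes boosted four-fold in one
  tissue (fold 4 keeps calls robust under noise while the calling rule
  only requires 2), multiplicative log-normal noise (sd 0.2 by default;
  recovery tests use 0).
* **TF peaks**: 30 TFs in 5 groups preferring I1, E1, E2, E3 and F1 —
  all gene-proximal states, so functional binding has annotatable
  targets. 80% of each TF's 60 peaks are planted in preferred-state bins
  inside the footprints of 40 functional target genes; the rest are
  uniform background. Peak widths are 200–400 bp.
* **Co-expression**: integer ranks 1..G per TF (ATTED-style semantics);
  functional targets draw ranks below a ceiling of 100 — the thresholds
  scale with the 500-gene universe the way the published 2000/27k
  thresholds scale with a real genome.

One global seed expands into per-stream child seeds (genome / peaks /
expression / co-expression), so regenerating one layer never perturbs the
others, and identical configs give byte-identical files.

What the generator does *not* emulate: read-level noise and mappability,
correlated replicate structure, overlapping or nested genes, non-uniform
chromosome sizes, distal (enhancer-like) functional binding, and
segmentation errors — state labels are exact. Passing recovery tests
therefore demonstrate correctness of the analytics, not robustness to
segmentation noise in real data.

# Numerical choices

* Weighted quantiles (signal-by-state summaries) use the inverse-CDF
  (type 1) definition, which agrees exactly with the per-bp expansion —
  enabling exact oracle tests.
* Odds ratios use the Haldane correction only when a cell is zero.
* All per-bp operations are validated against naive per-bp scans on
  randomized genomes ≤ 100 kb (100 trials), and the exact tests against
  closed-form enumeration for $N \le 200$ at $10^{-12}$.
* Test problem sizes: oracle trials use 20–50 kb genomes; recovery tests
  use the full 1 Mb default conditions, which run in seconds.

# Limitations

* The neighbourhood background is uniform; GC- or accessibility-aware
  backgrounds are not implemented.
* Target annotation is TSS-centric; distal regulatory assignment (e.g.
  by chromatin loops) is out of scope.
* The activity test treats genes as exchangeable under the null; gene
  length or expression-level biases in peak assignment are not modelled.
* `unassigned` handling assumes uncalled bins are missing at random;
  systematically unmappable compartments will bias genome fractions.
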