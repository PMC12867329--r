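Package: chromTF
Title: Chromatin-State Annotation and Transcription-Factor Activity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analytics for ChromHMM-style chromatin-state
    segmentations in plants and a framework for scoring transcription-factor
    occupancy and activity across chromatin states. Provides readers for
    segmentation BED, GFF3 gene models, narrowPeak/BED peak sets, emission
    tables, TPM matrices and co-expression rank tables; per-state genome
    statistics, feature composition, TSS/TTS neighbourhood enrichment,
    chromatin-domain classification and nomenclature; association of states
    with expression (TPM/CV binning, promoter state profiles, tissue
    specificity); comparison of state models (transition matrices, Jaccard,
    emission clustering, coordinate validation); Fisher-exact TF activity
    scores with hierarchical clustering and family enrichment; and a seeded
    synthetic-epigenome generator with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'states.R'
    'compare.R'
    'domains.R'
    'io.R'
    'expression.R'
    'tfscore.R'
    'synthio.R'
    'pipeline.R'
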