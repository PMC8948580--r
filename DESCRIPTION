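Package: TregTrace
Title: Paired-Chain TCR Clonotype Calling and Tissue-Provenance Statistics
    for Regulatory T Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for characterizing tissue regulatory T
    cells (Tregs). Reads single-cell V(D)J contig tables (10x-style CSV or
    AIRR Rearrangement TSV), resolves each cell to one productive TCR-alpha
    and one productive TCR-beta chain, and collapses cells into paired-chain
    clonotypes. Computes repertoire clonality statistics: the clonal
    expansion ratio (fraction of cells in clonotypes of two or more cells),
    the Gini inequality coefficient of clone sizes with its Lorenz curve,
    pairwise repertoire overlap and cross-sample clonotype sharing.
    Implements tissue-provenance arithmetic for parabiosis experiments
    (aorta-to-blood chimerism normalization and the multi-step
    recruitment-fraction estimate) and photoconversion migration ratios
    normalized to a nondraining lymph node. Scores differential-expression
    tables against canonical up/down gene signatures (concordant fraction)
    and counts fold-change genes. Ships deterministic synthetic-data
    generators with ground-truth records so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, ImmunoOncology, Software
RoxygenNote: 7.3.3
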