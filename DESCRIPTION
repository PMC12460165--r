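Package: STATscore
Title: STAT Pathway Activity Scoring from Cytokine-Stimulation RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives STAT-driven gene signatures from bulk RNA-seq of
    cytokine-stimulated T cells and scores samples for STAT pathway activity.
    Differentially regulated genes for each reference cytokine versus an
    unstimulated control are called with a negative-binomial Wald test and
    Benjamini-Hochberg correction; per-STAT driven sets are built by the
    cytokine-to-STAT mapping (IFNa -> STAT1, IL-4 -> STAT6, IL-10 and IL-21
    intersected -> STAT3, IL-2 and IL-7 intersected -> STAT5) and reduced to
    cross-STAT-exclusive sets; each sample's STAT score is the mean Pearson
    correlation of its TPM profile over the exclusive set to the reference
    cytokine-treated samples, with fold changes versus control and PCA on the
    score matrix. Includes a seeded negative-binomial simulator of the
    six-cytokine stimulation design with partial-agonist (attenuated) query
    conditions and ground truth for recovery testing, plus an end-to-end
    pipeline with manifest-based reproducibility checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
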