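Package: stemsc
Title: Rank-Based Stemness Scoring for Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("StemSC", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a cross-dataset stemness index for bulk and
    single-cell transcriptomes built on relative expression orderings
    (REOs) of gene pairs. Provides tools to identify stable gene-pair
    orderings within a dataset, quantify their cross-dataset consistency
    with a cumulative binomial model, train a directed gene-pair reference
    signature from embryonic stem cell pools, score arbitrary samples as
    the fraction of reference pairs whose ordering they preserve, and run
    downstream analyses: marker ranking, pre-ranked gene-set enrichment,
    threshold calibration against validated cancer stem cells, trajectory
    root selection, and highly variable gene selection. Because scores
    depend only on within-sample ranks they are invariant to per-sample
    monotone transformations (RPKM/TPM/log) and robust to batch effects.
    A synthetic-data module generates differentiation time courses, ESC
    reference pools, batch distortions, dropout and tumor mixtures with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
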