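Package: trajdeg
Title: Trajectory Classification and Transcriptional Coordination of
    Differentially Expressed Genes Across a Stimulus-Deprivation Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies per-gene expression trajectories across a three-group
    design (control, chronically stimulated, stimulated-then-deprived), flags
    genes whose altered expression persists after stimulus removal as
    pathology-associated, and quantifies per-group transcriptional
    coordination as counts of significantly correlated gene pairs. Includes
    per-gene two-group differential expression testing (Welch t or
    Mann-Whitney on log2-transformed FPKM-like values) with
    Benjamini-Hochberg false-discovery control, neurotransmitter gene-panel
    summaries, a synthetic bulk-expression simulator with planted trajectory
    classes and planted per-group co-expression, and an end-to-end pipeline
    driver producing tabular and plain-text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
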