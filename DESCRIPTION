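Package: senesceq
Title: Quantitative Metrics for Epithelial Stem-Cell Senescence Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of replicative senescence in
    epithelial stem-cell cultures: clonogenicity and cumulative population
    doubling metrics from serial passage records, qPCR delta-delta-Ct relative
    quantification, an FPKM time-series preprocessing and monotone-trend
    selection pipeline with housekeeping and baseline normalization,
    slope-comparison (ANCOVA) and multiple-range statistics, Fisher's exact
    gene-set overrepresentation with false-discovery-rate control, and
    fluorescence image quantification (per-cell relative telomere length from
    Q-FISH spot signals, corrected total cell fluorescence for diffuse
    staining). A seeded synthetic-data module generates every input the
    pipeline consumes, with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
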