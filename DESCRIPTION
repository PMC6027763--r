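Package: tauquant
Title: Rater-Independent Quantification of Tau Pathology in Fluorescence Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated, rater-independent measurement of phospho-tau
    immunoreactive area and ThioflavinS plaque load in multi-channel
    fluorescence micrographs of cortical sections, together with the
    study-level aggregation and statistics used to compare Braak stage
    groups: lowpass background correction, autofluorescence mask
    subtraction, edge-enhanced threshold segmentation with size and shape
    restrictions, plaque-core versus tangle discrimination, isocortex
    averaging, fold change versus controls, and one- and two-way ANOVA
    with Bonferroni, Tukey and Newman-Keuls post-hoc families. Includes a
    synthetic histology-section generator with per-class ground-truth
    masks so that every stage of the pipeline is testable without human
    tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    png,
    yaml,
    car,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
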