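Package: lectinrules
Title: Lectin Specificity Annotation from Glycan Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for annotating the glycan-binding
    specificity of lectins from glycan-microarray fluorescence data. Parses
    branched glycan structures written in the CFG/IUPAC-condensed dialect
    into rooted labelled trees, featurizes glycan libraries with a curated
    motif catalog plus systematically enumerated mono- and disaccharide
    motifs, converts replicate spot fluorescence into Stouffer-combined,
    background-corrected Z-scores with quality-control filters, mines
    interpretable conjunctive binding rules from shallow tree ensembles,
    clusters lectins by binding profile (average-linkage, Pearson distance),
    and assembles per-lectin annotation reports with enhancer and inhibitor
    candidates. Includes a synthetic-data generator with planted binding
    motifs so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
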