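Package: barseqcomp
Title: Barcode-Based Multi-Strain Competition Analysis Under a Sporulation Bottleneck
Version: 0.1.0
Authors@R: person("Maintainer", "Unknown", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing pooled multi-strain competition experiments
    tracked by strain-specific DNA barcodes (Bar-seq). Includes a forward-time
    simulator of serial-transfer experiments with a heat-kill sporulation
    bottleneck, a synthetic paired-end amplicon read generator with known
    ground truth, inline-tag demultiplexing and exact barcode counting,
    population-dynamics summaries (frequency trajectories, persistence,
    winner detection), CFU-based relative and sporulation fitness estimators
    for pairwise competitions, and supporting statistics (Euclidean-distance
    PERMANOVA implemented from first principles, scaled PCA, Spearman
    input-output correlation with multiplicity adjustment, and growth-curve
    increments).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
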