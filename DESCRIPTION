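Package: helptagdm
Title: Differential DNA Methylation Analysis for HELP-Tagging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for genomewide differential DNA
    methylation from HELP-tagging data: per-locus methylation scores on the
    0-100 scale from paired methylation-sensitive (HpaII) and
    methylation-insensitive (MspI) tag counts, confidence-based locus
    filtering and sample quality control, per-locus two-group t-tests with
    candidate-locus gates, permutation-based significance correction and
    power calibration, run-based detection of differentially methylated
    regions, window-based mapping of loci to gene models, gene-set
    enrichment corrected for per-gene HpaII-site-count bias by weighted
    resampling, and downstream 2^-ddCt relative-expression analysis with
    ANOVA and Tukey HSD. Includes a calibrated synthetic-data generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
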