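Package: swagmeth
Title: Sparse Wrapper Model Selection for Epigenome-Wide Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for two-group epigenome-wide
    association studies on Illumina-style methylation arrays. Implements the
    sparse wrapper algorithm (SWAG) for building libraries of low-dimensional
    logistic classification models over CpG beta-values scored by AIC, with
    frequency-based variable importance; negative-control background
    normalisation, bead-count and detection p-value probe filtering, and
    beta-value computation from raw intensities; vectorised per-probe Welch
    and pooled t-tests with direction calls and summary-statistics t-tests;
    CpG island / RefGene manifest annotation with genomic-context
    distributions; gene-set cross-comparison with Benjamini-Yekutieli false
    discovery rate control; and a seeded synthetic EPIC-like data generator
    with planted differential probes for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
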