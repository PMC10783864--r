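Package: lysPTM
Title: Multi-Label Recognition of Lysine Post-Translational Modification Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes four types of lysine post-translational modification
    (acetylation, crotonylation, methylation and succinylation) from
    fixed-length peptide segments centered on a lysine residue. Segments are
    encoded by location-fixed di-residue distribution features estimated from
    a training set, and labels are scored by a per-label masked Gaussian
    kernel regression engine (with the unmasked Gaussian kernel regression
    baseline also available). Includes multi-label evaluation metrics
    (aiming, coverage, accuracy, absolute true, absolute false), per-label
    confusion metrics with ROC/PR areas, general and protein-grouped
    cross-validation drivers with per-fold feature refitting, a synthetic
    multi-label peptide dataset generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
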