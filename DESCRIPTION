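Package: trescan
Title: Discovery of Thyroid Hormone Response Elements in Promoter Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: In-silico discovery of thyroid hormone response elements (TREs)
    in TSS-anchored promoter windows. Builds a hexamer half-site position
    weight matrix (bit-score, log-odds against a background composition) from
    a training set of validated half-sites, scans promoters for DR4, IR0 and
    ER6 candidate elements under a dual (low/high) bit-score threshold rule,
    and filters candidates by cross-species conservation against rat and
    human ortholog promoters (ungapped sliding-window alignment, half-site
    mismatch and positional-distance criteria). Includes a classifier that
    selects candidate directly hormone-regulated genes from fold-change
    tables across hypothyroid, hyperthyroid and hormone-replacement treatment
    groups, and a seeded synthetic-data generator that plants elements at
    known positions so the whole pipeline can be benchmarked for recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
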