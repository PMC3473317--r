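Package: cellsig
Title: Cell-Type Enrichment from Highly Expressed Cell-Specific Gene Signatures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds highly expressed cell-specific (HECS) gene signature
    databases from expression atlases (probes x samples intensity matrices
    spanning many purified cell types), scores user gene lists for cell-type
    enrichment with a one-sided Fisher's exact test and Benjamini-Hochberg
    adjustment, ranks multi-list results for cross-list heatmaps, and provides
    validation machinery: top-percentile test-list generation, rank evaluation,
    ROC curves with bootstrap confidence intervals, signature-threshold
    robustness sweeps, and gamma-based null calibration from random gene
    lists. A synthetic atlas generator with planted signatures supplies ground
    truth for end-to-end testing without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
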