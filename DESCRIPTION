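Package: troopcall
Title: Acoustic Coordination of Collective Movements in Primate Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how acoustic signals coordinate collective
    movements in primate troops. Provides bioacoustic feature extraction
    (autocorrelation fundamental-frequency tracking, call-type classification),
    social-network metrics (dyadic association index, eigenvector centrality by
    power iteration, David's Score dominance ranking, matrilineal kinship
    counts), collective-movement analytics (event segmentation, joining-order
    index, vocal tallies), a statistical battery (Mann-Whitney U with exact
    enumeration, Spearman rank correlation, zero-inflated Poisson regression
    with Wald tests), a synthetic-data generator with known ground truth for
    every stage, and an end-to-end pipeline producing result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    glmmTMB
Config/testthat/edition: 3
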