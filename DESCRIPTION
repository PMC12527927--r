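Package: gatescore
Title: Genome-Wide Aggregated Trans-Effects Analysis for Core-Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-gene polygenic scores that aggregate trans-acting QTL
    effects on gene expression or protein levels (GATE scores), tests them for
    case-control disease association, and interprets the results under the
    omnigenic/core-gene model. Provides clumping and LD adjustment of marginal
    QTL summary statistics, exclusion of the HLA trans-hotspot, correlation-based
    clustering of scores, putative core-gene calling, information-for-
    discrimination estimates with dilution correction, and Mendelian
    randomization that marginalizes over pleiotropic instrument effects with a
    horseshoe shrinkage prior. A synthetic-data generator emulating an
    LD-blocked genotype panel with a sparse core-gene trans-regulatory
    architecture makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
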