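Package: rhceqtl
Title: Copy-Number Expression QTL Mapping in Radiation Hybrid Panels
Version: 0.1.0
Authors@R: person("RH", "Genomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping copy-number expression quantitative trait
    loci (ceQTLs) in radiation hybrid (RH) panels. Simulates RH panels with
    known donor-fragment retention structure, normalizes bimodal aCGH
    log-ratio data by mode centering and scaling, fits a linear dosage
    model with a pooled permutation null and per-class Benjamini-Hochberg
    FDR, and provides downstream statistics: trans-hotspot Poisson tests,
    noncoding block construction and cross-species matching, sign
    concordance between datasets, X-chromosome dosage-attenuation tests,
    and Frobenius-norm comparison of gene-gene correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
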