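Package: threefloors
Title: Product Chain-Length Prediction for trans-Prenyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the predominant product chain length of trans-prenyltransferases
    (FPP C15, GGPP C20, GFPP C25, or longer polyprenyl pyrophosphates) from protein
    sequence alone, using the "three floors" model of the product elongation tunnel.
    A query is globally aligned against a registry of structural templates, the nine
    tunnel floor residues are projected onto the query, per-floor weighted blocking
    scores are computed from side-chain bulk and torsional rigidity, and a threshold
    cascade calls the product class. Includes calibration of site weights and floor
    thresholds from labeled data, accuracy accounting with per-kingdom and
    per-template breakdowns, and a synthetic floor-site mutant generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
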