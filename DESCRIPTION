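Package: chronocal
Title: Distance-Calibrated Divergence-Time Placement of New Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for placing a newly discovered taxon on a published
    time-calibrated phylogeny using uncorrected p-distances. Computes
    pairwise-deletion p-distance matrices from aligned sequences,
    extracts species-pair divergence times from an ultrametric
    chronogram, fits a time-versus-percent-distance calibration line
    (through the origin or unconstrained), and predicts the minimum
    divergence time of a focal species with uncertainty. Includes a
    strict-clock Yule + Jukes-Cantor simulator for end-to-end
    validation of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
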