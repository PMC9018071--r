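Package: atpflux
Title: Single-Cell ATP Dynamics and Protein-Aggregation Kinetics from
    Ratiometric Biosensor Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intracellular ATP in single yeast cells from
    dual-excitation (410/490 nm) QUEEN biosensor time-lapse image stacks,
    classifies per-cell ATP dynamics (stable, ATP dip, shallow dip, ATP
    shift) with fixed-threshold rules on the QUEEN ratio, detects protein
    aggregate (Hsp104 reporter) foci by prominence-based local-maxima
    analysis, and links transient ATP depletion to accelerated aggregate
    accumulation through a pre-dip linear-regression RMSD statistic.
    Includes autocorrelation-based period estimation for oscillatory ATP
    traces and a synthetic-data generator producing traces and image
    stacks with known ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
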