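Package: arsdetect
Title: Area-Restricted Search Detection and Validation in Central-Place
    Forager Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects area-restricted search (ARS) zones in GPS tracks of
    central-place foraging seabirds by first-passage time analysis and
    penalized-contrast (Lavielle) change-point segmentation, crosses the
    detected zones with accelerometer- and depth-derived time budgets, and
    flags zones driven by resting at the sea surface rather than active
    search. Includes constant-step track rediscretization, a per-second
    ethogram classifier for two-axis acceleration and depth records, plunge
    dive detection, binomial (mixed) models of ARS occurrence with posterior
    simulation, a deviance-based classification tree with jack-knife
    validation, and a seeded generator of synthetic foraging trips for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    geosphere,
    jsonlite,
    lme4,
    MASS,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tree,
    withr
Config/testthat/edition: 3
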