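Package: synopticr
Title: Synoptic River-Network Solute Chemistry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of synoptic (snapshot) stream-network water chemistry
    surveys. Computes the three ecohydrological metrics used to locate and
    characterise solute sources in river networks: spatial-variance
    changepoints of scaled concentration over subwatershed area (a from-scratch
    PELT implementation with an exhaustive optimal-partitioning oracle),
    subwatershed leverage on outlet flux with critical-source-area
    classification, and spatial persistence of concentration rankings across
    seasons via Spearman rank correlation. Also provides factorial ANOVA with
    Tukey post-hoc comparisons, all-subsets regression selected by AICc, a
    synthetic watershed generator that reproduces the statistical structure of
    semiarid river-network surveys (nested subwatershed areas, point sources,
    hourglass spatial variance, solute-specific rank persistence), and a
    reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
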