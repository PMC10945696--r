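Package: flyarena
Title: Behavioral Quantification for Four-Quadrant Optogenetic Fly Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying group behavior of walking flies in a
    four-quadrant circular arena with optogenetic LED stimulation and
    odorized airflow drawn out at the center. Ingests tracker-output
    trajectory tables, builds labeled stimulus schedules (olfactory
    conditioning, repeated LED activation, lit-quadrant preference),
    computes per-frame kinematics (walking speed, absolute angular change,
    cosine of upwind orientation, distance from center, windowed cumulative
    turning), epoch-locked stimulus summaries (ON/OFF window means, change
    in distance from center, return-to-place probability), quadrant
    preference indices with reciprocal-design memory scores, z-score
    screening matrices across genotype lines, and tie-corrected
    Kruskal-Wallis with Dunn's many-to-one post tests. A seeded correlated
    random-walk cohort simulator emulates the assay so every pipeline stage
    is testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
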