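Package: saltmig
Title: Quantification of Cyclic Saltatory Neuronal Migration from
    Time-Lapse Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the cyclic saltatory migration of neurons
    tracked in time-lapse microscopy, as used for postnatal rostral
    migratory stream neuroblasts. Detects nucleokinesis (NK) events from
    supra-threshold inter-frame nuclear displacements and centrokinesis
    (CK) events from rise-and-fall excursions of the centrosome-nucleus
    separation, classifies CK efficiency, and computes per-cell migration
    metrics (speed, pausing time, sinuosity, migration angle, NK/CK
    frequency and amplitude) together with four-dial directionality
    radars. Includes the nonparametric statistical layer used for group
    comparisons (Kruskal-Wallis with Dunn's post hoc test, Mann-Whitney,
    Pearson chi-square, Fisher's exact test with Monte-Carlo support for
    RxC tables, Benjamini-Hochberg correction, median/IQR summaries) and
    a stochastic simulator of saltatory nucleus plus centrosome tracks
    with genotype presets and per-event ground truth for validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
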