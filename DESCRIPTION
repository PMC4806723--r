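Package: invasiontraits
Title: Trait-Based Comparison of Invasive and Native Desert Annuals
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing the ecophysiology of co-occurring invasive
    and native winter annual plants: permutation inference on integrated
    diurnal leaf water loss from stomatal conductance curves,
    sequential-harvest growth analysis (relative growth rate, net
    assimilation rate and allocation components such as SLA, LAR, LMR and
    root mass ratio), carbon isotope discrimination, the relative
    interaction intensity (RII) index for neighbour-manipulation
    competition experiments, and a blocked factorial test of the enemy
    release hypothesis. A shared least-squares engine provides fixed-effect
    and one-random-blocking-factor ANOVA/ANCOVA tables, and
    seed-reproducible synthetic-data generators emulate the four underlying
    experimental designs for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
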