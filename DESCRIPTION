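Package: pisacalc
Title: Periodontal Inflamed Surface Area (PISA) Calculation, Simulation and
    Cohort Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the periodontal epithelial surface area (PESA) and the
    periodontal inflamed surface area (PISA) from full-mouth six-site probing
    charts under two published formula systems: a Japanese linear-slope
    version derived from extracted-tooth attachment measurements and the
    original degree-six polynomial version. Provides validated chart
    import/export in tidy tabular formats, a uniform-probing-depth simulation
    comparing the two versions (per tooth type and whole mouth, with
    crossover localisation and version ratios), a calibrated synthetic-cohort
    generator emulating published cross-sectional summaries, and the paired
    nonparametric and regression analyses used to validate the Japanese
    version against the original.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
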