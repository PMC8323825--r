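Package: microforce
Title: Cantilever-Beam Force and Dimpling Analysis for Microelectrode
    Insertion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cantilever-beam based measurement of
    insertion forces and brain-surface dimpling during microelectrode
    implantation. Implements the closed-form Euler-Bernoulli calibration
    mechanics of the sensing beam (flexural rigidity, force and
    deflection ratios, measurement capacity, tilt error) and the Euler
    critical buckling load of slender microwires; converts laser
    displacement traces sampled at 500 Hz into force, beam-deflection,
    stage and dimpling channels and detects membrane rupture events;
    simulates physiologically structured insertion traces (breathing
    oscillation, sensor quantization, rupture drop, post-rupture
    plateau) and whole factorial insertion studies; and provides the
    study-level statistics: buckling-rate tables, diameter-linearity
    fits on condition means, main-effects ANOVA with type II sums of
    squares, Pearson correlation strata, and dimpling-to-force ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
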