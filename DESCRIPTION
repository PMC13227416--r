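Package: cardiomorph
Title: Quantification of Heart Tube Closure and Cardioblast Migration Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the tissue and cell dynamics of Drosophila heart tube
    formation from time-lapse annotations. Provides luminal polygon
    morphometrics (area, perimeter, circularity, caliper axis lengths),
    threshold-based time registration, exponential closure-rate fitting,
    cardioblast migration speed, oscillation period and medial/lateral step
    decomposition from nuclear centroid tracks, female-versus-male group
    comparison with exact Mann-Whitney tests, a ground-truth synthetic data
    generator, and kymograph construction from image stacks.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
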