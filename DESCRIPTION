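Package: equiplume
Title: Emission Estimation and Dispersion of Horse Allergen and Odor
    Around Equine Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating airborne horse-allergen and ammonia emissions
    from equine facilities (stable ventilation outlets, pastures, manure heaps)
    and dispersing them to receptor grids with an hourly Gaussian-plume model.
    Includes inverse dispersion estimation of pasture area-emission rates from
    receptor measurements, passive flux-sampler integration of manure-heap
    ammonia emissions, diurnal and seasonal emission distribution indices,
    odor walk-survey analysis with logistic detection-distance models, and a
    seeded synthetic-data generator so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
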