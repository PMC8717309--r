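Package: endolink
Title: Endozoochorous Seed Dispersal Analysis for a Mammalian Mobile Linker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying endozoochorous seed dispersal by a
    medium-sized mammalian herbivore from a controlled feeding experiment
    and GPS tracking. Computes seed dispersal syndrome trait indices
    (eccentricity, flatness, density, dimensional shape variance, surface
    area) and germination success after gut passage standardized by control
    germination capacity; fits a Bayesian phylogenetic mixed model (animal
    model) by Gibbs sampling with DIC-based all-subsets model selection and
    Lynch's phylogenetic heritability; and measures moving-window habitat
    connectivity from hourly GPS fixes over polygonal land-use mosaics at
    gut retention time scales. Includes deterministic simulators for
    pure-birth phylogenies, Brownian trait evolution, trait-driven
    germination with a phylogenetic random effect, mosaic landscapes, and
    correlated-random-walk movement tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
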