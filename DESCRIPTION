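Package: colonyfba
Title: Three-Dimensional Dynamic Flux Balance Analysis of Bacterial
    Colony Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of bacterial colonies on structured agar
    substrates by coupling an explicit reaction-diffusion solver on a regular
    cubic lattice with per-site dynamic flux balance analysis (dFBA) read from
    precomputed flux lookup tables. Implements the two-phenotype (glucose
    utilizer / acetate utilizer) description of Escherichia coli acetate
    cross-feeding, strain parameterization from chemostat exchange-rate tables
    or genome-scale metabolic models, six parametric substrate geometries
    (flat, wall, plateau, hole, concave, convex), isotropic biomass pushing at
    a packing cap, phenotype regulation under glucose starvation, and analysis
    tools for phenotype fractions, cross-feeding onset times, colony
    dimensions, axis concentration profiles, acetate turnover, and
    grid-convergence error reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
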