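Package: dietfront
Title: Multi-Objective Optimization of Food-Based Dietary Guidelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the cost-emissions-nutrition trade-off space of
    national food-based dietary guidelines (FBDGs). Translates food-group
    recommendations into commodity-level diets with mass-balance preservation,
    recipe disaggregation and nutrient imputation; compiles six protein/nutrient
    scenarios into constraint sets over an eight-dimensional animal-source-food
    intake vector; searches the trade-off space with a penalty-constrained
    NSGA-II and exact Pareto machinery; and quantifies robustness with Monte
    Carlo uncertainty propagation, convergence checking and graduated
    sensitivity/elasticity analysis. Includes a seeded synthetic-data generator
    for four country archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
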