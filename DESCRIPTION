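Package: commfba
Title: Balanced-Growth Community Flux Balance Analysis with Hierarchical
    Yield Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles single-species stoichiometric metabolic models into
    balanced-growth community models in which every member grows at the common
    community growth rate and relative abundances enter as biomass fractions on
    the simplex. Community composition is predicted by hierarchical
    optimization: the community growth rate is maximized first, then the
    yield-weighted total substrate consumption is minimized, and the optimality
    degree (the ratio of the two optima) quantifies how close each composition
    is to simultaneous maximum-yield growth of all members. Includes SBML
    import/export for constraint-based models, flux balance analysis and flux
    variability on top of a linear-programming layer, composition and
    growth-rate scans with minimum product rates and yields (solved as
    linear-fractional programs), Pirt-type maintenance-energy estimation from
    chemostat data, cell-geometry dry-weight conversion, and parametric toy
    cross-feeding communities with closed-form optima for testing.
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
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
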