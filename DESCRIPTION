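Package: comfba
Title: Multilevel Flux Balance Analysis for Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling of microbial communities by
    multilevel optimization. Each community member is described by a
    stoichiometric model whose biomass-maximization linear program forms an
    inner problem; members are coupled through mass balances on a shared
    metabolite pool and a community-level outer objective. The package
    provides a predictive mode (every species certified at its inner optimum,
    solved to global optimality through single-level KKT reformulations), a
    descriptive mode that quantifies per-species optimality levels against
    community-specific growth maxima, a typology of ecological interactions
    encoded as inter-organism flow constraints, community-level flux
    variability analysis, a brute-force grid oracle for independent
    verification, deterministic toy-community fixtures, readers for SBML-FBC
    and a compact JSON model dialect, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
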