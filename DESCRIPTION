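Package: oleoflux
Title: Constraint-Based Flux Analysis of Lipid Production in Oleaginous Yeast
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis (FBA) infrastructure for studying lipid
    production in oleaginous yeasts such as Rhodotorula toruloides grown on
    low-cost carbon sources (glycerol, xylose, acetate). Provides S4 containers
    for stoichiometric metabolic models with elemental bookkeeping, readers and
    writers for SBML Level 3 (fbc) and a documented JSON dialect, a first-
    principles bounded-variable simplex solver for FBA, flux variability
    analysis and random-objective vertex sampling of the solution space, a
    condition-specific modeling pipeline (biomass-composition rescaling,
    measured-rate constraining with exchange-flux relaxation, non-growth
    associated maintenance estimation, flux attribution to NADPH- and
    acetyl-CoA-producing pathways), theoretical maximal lipid-yield
    computation, turbidostat physiology calculators (rates, yields,
    respiratory quotient, carbon recovery, medium C/N ratio), and an
    exponential fed-batch feeding designer with a mass-balance bioreactor
    simulator. A hand-built, carbon-balanced toy genome-scale model and a
    noisy measurement generator make the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Metabolomics, SystemsBiology, Software
RoxygenNote: 7.3.3
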