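Package: crperturb
Title: Consumer-Resource Communities Under Species-Specific Antibiotic Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemostat consumer-resource model of microbial communities with
    species-specific death rates, as induced by narrow-spectrum antibiotics,
    bacteriophages or other growth-inhibiting perturbations. Provides the
    geometric (convex-hull) coexistence machinery on the resource simplex, a
    direct steady-state solver and an ODE integrator with extinction and
    richness criteria, plus analysis pipelines for antibiotic dose scans,
    sequential treatments (non-transitivity: promotion and neutralization),
    antibiotic combinations (non-additivity: synergism and antagonism),
    Monte-Carlo community ensembles, metabolic leakage (cross-feeding) and
    its reduction to shifted supply rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
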