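Package: cd4kinetics
Title: Multiscale Modelling of Age-Dependent CD4+ T-Lymphocyte Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A physiologically-based compartmental model of CD4+ T-lymphocyte
    homeostasis across the human lifespan. Couples a thymocyte maturation
    submodel (thymic involution through shrinking cortical and medullary
    carrying capacities) to six peripheral CD4+ subpopulations (recent thymic
    emigrants, naive, activated, central-memory, effector-memory, effector)
    trafficking between blood, lymphoid tissue, the gastro-intestinal tract
    and lungs. Age-dependent modulation of kinetic rates is expressed through
    hyperbolic (Hill-type) functions of age or through cell-concentration
    feedback on recent thymic emigrants. Includes proportional-error
    maximum-likelihood calibration with multi-start optimisation and AIC
    stepwise selection of age functions, profile-likelihood identifiability,
    Latin-hypercube/PRCC global sensitivity analysis, thymectomy and
    adaptation-knockout perturbation simulations, and a synthetic-data
    generator emulating age-binned calibration datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
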