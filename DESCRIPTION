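Package: grksim
Title: Dynamic EGFR Signaling on a Growing Drosophila Egg Chamber
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the secretion, diffusion and receptor-mediated uptake of
    the TGF-alpha-like ligand Gurken in the perivitelline space of a growing
    Drosophila egg chamber, together with EGFR trafficking, dpERK signal
    production and STY/KEK1 negative feedback in the overlying follicle cells.
    The perivitelline space is modeled as a prolate spheroid that grows in time;
    ligand diffusion uses a finite-volume discretization of the time-varying
    Laplace-Beltrami operator on a multi-zone cubed-spheroid mesh, coupled by
    operator splitting to growth transport, a posterior follicle-cell shift and
    local reaction kinetics. Includes a moving T-shaped ligand source tracking
    the oocyte nucleus, mechanistic perturbation presets (nucleus stop, growth
    stop, follicle-cell shift removal, ligand dosage, sty/EGFR depletion),
    intensity-profile extraction along the anterior-posterior and dorsal-ventral
    axes, L1 model-data error metrics, and grid calibration of the inhibitor
    strengths against reference intensity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
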