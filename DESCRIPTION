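Package: hydroshell
Title: Structure and Dynamics of Polymer Hydration Water from Neutron
    Scattering and Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native analysis pipeline for supercooled hydration
    water around water-soluble polymers such as poly(ethylene glycol).
    Covers quasi-elastic neutron scattering reduction (elastic-scan
    construction and onset detection, Fourier transformation of S(q,dE) to
    the intermediate scattering function, Kohlrausch-Williams-Watts
    stretched-exponential fitting and q-power-law scaling of relaxation
    times), Arrhenius and super-Arrhenius (Vogel-Fulcher-Tammann)
    relaxation kinetics with low-temperature extrapolation and crossover
    location, small-angle neutron scattering contrast variation
    (zero-average-contrast forward model, match-point determination,
    excluded-volume chain form factors), and molecular-dynamics trajectory
    observables (geometric hydrogen-bond detection, intermittent and
    continuous bond correlation functions, radial distribution functions,
    incoherent intermediate scattering functions, water volume
    distributions and confining lengths, trap-and-jump diffusion
    statistics). A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable without instruments or
    simulations.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
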