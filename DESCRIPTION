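Package: t1ept
Title: Electrical Property Estimation from Inversion-Recovery T1 Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating tissue-mimicking
    phantom permittivity and conductivity from multi-TI inversion-recovery MRI.
    Generates a 140-phantom water/sucrose/NaCl/KCl cohort with dielectric
    ground truth and probe-style replicate measurements, simulates
    inversion-recovery image stacks, maps the zero-crossing time T0 = T1*ln(b)
    pixel-wise by nonlinear least squares, and estimates electrical properties
    with Debye-type curve-fit models, Gaussian process regression, a linear
    baseline and a one-hidden-layer neural fit, with map-level
    region-of-interest evaluation comparing the approaches.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    minpack.lm,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
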