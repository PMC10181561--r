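Package: meepi
Title: Simulation and Evaluation of Multi-Echo EPI Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify what multi-echo echo-planar imaging (EPI)
    buys over single-echo acquisition in resting-state BOLD fMRI. Provides
    a synthetic multi-echo phantom with fully known ground truth
    (mono-exponential TE decay, planted low-frequency networks,
    physiological, motion, drift and thermal noise), T2*-weighted optimal
    echo combination, nuisance regression with marginal explained-variance
    partitioning, SNR/TSNR metrics, ROI/seed/dual-regression functional
    connectivity with false-discovery-rate control, network-detection
    sensitivity/specificity/accuracy versus scan length, and EPI
    acquisition-timing arithmetic (echo spacing, readout duration, Ernst
    angle, TSNR-time efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
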