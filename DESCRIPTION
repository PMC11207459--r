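Package: mrmotion
Title: Simulation and Processing of MRI-Compatible Motion Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and processes three MRI-compatible motion-sensing
    pipelines at desk scale: a Pilot-Tone radiofrequency transmitter whose
    amplitude, extracted from raw radial k-space, is calibrated against
    image-derived liver displacement and used for motion-gated non-uniform
    Fourier reconstruction; a single-element 1 MHz A-mode ultrasound
    (organ-configuration-motion) sensor used to predict mid-sagittal bladder
    area with a 1D convolutional network; and a Time-of-Flight depth camera
    from which a respiratory waveform is extracted. Includes a parametric
    breathing phantom and raw-sensor simulators with known ground truth,
    small fully-connected and convolutional networks trained with
    Adam/AdamW, gated radial reconstruction, and simultaneous
    multi-sensor stream alignment and correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
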