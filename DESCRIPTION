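Package: v1tune
Title: Visual Cortex Tuning, Familiarity-Evoked Oscillations, and Population Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for awake-mouse primary visual cortex (V1)
    electrophysiology: Morlet-wavelet time-frequency decomposition and
    intertrial phase coherence of layer-IV local field potentials,
    single-unit tuning quantification (orientation selectivity and
    double-Gaussian direction fits, difference-of-Gaussians spatial-frequency
    fits, hyperbolic-ratio contrast fits), a familiarity-evoked oscillation
    duration statistic, and linear-discriminant population decoding of
    stimulus identity from spike counts. A synthetic-cohort generator
    (inhomogeneous-Poisson spike trains plus multichannel LFP with
    genotype- and experience-dependent effects) provides ground-truth
    labelled recordings so every stage is verifiable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
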