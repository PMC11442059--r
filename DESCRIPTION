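Package: rnlvision
Title: Receptor-Noise-Limited Visual Modeling of Prey Conspicuousness
Version: 0.1.0
Authors@R: person("rnlvision", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for predator-vision analyses of animal
    coloration: preprocessing of raw reflectance spectra (trimming, negative
    clipping, LOESS smoothing, replicate averaging), construction of
    receptor-noise-limited (RNL) visual systems for avian, lizard and crab
    viewers (visual pigment templates, oil-droplet filtering, Weber-anchored
    receptor noise), quantum-catch computation, chromatic (deltaS) and
    achromatic (deltaL) contrasts in just-noticeable-difference units,
    distance-preserving perceptual-space coordinates, and information-theoretic
    multi-model inference (AICc weights, evidence ratios, model averaging)
    on the resulting contrast tables with random-intercept mixed models.
    Includes a synthetic-data generator emulating a two-species, two-morph
    poison-frog study design so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
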