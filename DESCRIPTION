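Package: nucmech
Title: Nuclear Mechanics and Chromatin Dynamics Analysis Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pipelines for studying how DNA damage changes the
    biophysical state of the cell nucleus. Implements atomic force microscopy
    (AFM) force-curve analysis with contact-point detection and a pyramidal-tip
    Hertz model, thermal-noise spring-constant calibration, multifocal-microscopy
    nine-plane movie reassembly with 3D single-particle tracking and
    anomalous-diffusion MSD fitting, electron-microscopy chromatin-condensation
    scoring, and high-content screening of gammaH2AX damage signalling in
    segmented nuclei. Each analysis stage is paired with a seeded synthetic-data
    generator with known ground truth, so parameter recovery can be verified
    end to end. Shared group statistics (mean +/- SEM, pooled-variance t-tests,
    significance annotation) are included for condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
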