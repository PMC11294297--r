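Package: renaldosim
Title: Kidney Dosimetry with Time-Varying Parenchymal Volumes for Lu-177 SPECT/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying how anatomical
    kidney-parenchyma volume changes during Lu-177-DOTATATE therapy bias
    SPECT/CT dosimetry. Provides voxel-grid and volume-of-interest (VOI) data
    structures with CT-to-SPECT resampling and VOI propagation strategies,
    parametric kidney/spleen phantoms with time-varying volumes and
    tri-exponential activity kinetics, Gaussian point-spread-function SPECT
    rendering, recovery-coefficient partial-volume correction, a constrained
    five-parameter tri-exponential time-activity fit with closed-form
    time-integrated activity concentration, local-energy-deposition absorbed
    dose, and Bland-Altman / paired-Wilcoxon agreement analysis, orchestrated
    by a config-driven cohort experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
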