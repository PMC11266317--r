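Package: spectac
Title: CT-Based Attenuation Correction Analysis for Quantitative 177Lu SPECT/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how CT acquisition parameters (tube voltage and
    quality-reference mAs) propagate into quantitative 177Lu SPECT/CT imaging.
    The package computes theoretical linear attenuation coefficients at the
    208.4 keV 177Lu emission from elemental mass-attenuation tables and the
    mixture rule, generates digital electron-density and NEMA-body quantification
    phantoms, emulates Hounsfield-unit volumes with setting-dependent noise,
    converts HU volumes to attenuation maps with a calibrated bilinear model,
    computes first-order Chang attenuation-correction-factor images by ray
    integration, provides VOI statistics and the coefficient-of-variation noise
    chain, and includes a small attenuated parallel-beam OSEM emulator for
    activity-recovery experiments.
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
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
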