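Package: thermodose
Title: MR Thermometry and CEM43 Thermal Dosimetry for Interstitial Ultrasound Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting thermal ablation zones from multislice 2-D
    magnetic resonance thermal imaging (MRTI). Converts wrapped-phase image time
    series into drift-corrected proton resonance frequency shift (PRFS)
    temperature maps (referenced polynomial correction or referenceless
    Goldstein-unwrapping background subtraction), accumulates Sapareto-Dewey
    CEM43 thermal dose, and estimates necrotic-zone volumes by isodose
    thresholding. Includes histology-style section volumetry, Bland-Altman /
    correlation / paired-t agreement analysis for method comparison, a
    Pennes-bioheat synthetic acquisition simulator with known ground truth for
    end-to-end validation, and minimal NIfTI-1 input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
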