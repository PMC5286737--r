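Package: cardiotherm
Title: Real-Time Cardiac MR Thermometry and Thermal Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motion-compensated proton resonance frequency shift (PRFS)
    temperature mapping for catheter-based radiofrequency ablation monitoring
    in the heart, with CEM43 thermal-dose accumulation, dose-uncertainty
    correction and lesion-size extraction. Includes a synthetic dynamic-MR
    phantom generator (respiratory motion, susceptibility phase coupling,
    field drift, localized heating, complex Gaussian noise) with analytic
    ground truth so the whole pipeline can be validated without scanner data,
    plus lesion-concordance statistics (Pearson correlation, regression,
    Bland-Altman agreement) for comparing thermal-dose lesion dimensions
    against post-ablation imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    RNifti,
    jsonlite,
    EBImage,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
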