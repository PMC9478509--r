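Package: bcsfbasl
Title: Blood-CSF Barrier and Cortical Perfusion Quantification from Multi-TI FAIR ASL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies water delivery across the blood-cerebrospinal fluid barrier
    (BCSFB) at the choroid plexus and cortical cerebral blood flow from multi-inflow-time
    flow-alternating inversion recovery (FAIR) arterial spin labelling (ASL) MRI.
    Implements closed-form single-compartment (tissue) and two-compartment (ventricular
    CSF) Buxton-type kinetic models, inversion-recovery T1/M0 relaxometry, ROI signal
    extraction with ventricular-volume M0 correction, T2-weighted ventricular
    morphometry, and two-group summary statistics. Ships a digital-phantom simulator
    with normotensive (WKY-like) and hypertensive (SHR-like) presets so the whole
    pipeline is testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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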