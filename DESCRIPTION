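Package: vfib
Title: Ventricular Fibrillation Dynamics and ECG Markers in Acute Ischaemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis pipeline for ventricular
    fibrillation (VF) under graded acute myocardial ischaemia. Provides a
    reduced human ventricular ionic model with hyperkalaemia, ATP-sensitive
    potassium current and acidosis modifiers, restitution and VF-induction
    pacing protocols, Latin-hypercube population calibration, a 2D monodomain
    tissue simulator with regional ischaemia and time-varying remote severity,
    infinite-medium pseudo-ECG computation at named bipolar electrode pairs,
    phase-singularity detection with an independent phase-winding oracle, and
    VF waveform markers (amplitude spectrum area, dominant frequency, median
    slope) with severity stratification of windowed measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    signal,
    MASS,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
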