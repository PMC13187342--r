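Package: betalens
Title: Acoustic-Lens Treatment Planning and Beta-Band LFP Analysis for
    Pulsed Transcranial Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for pulsed transcranial
    ultrasound (TUS) neuromodulation studies targeting the basal ganglia:
    personalised phase-conjugate acoustic lens design by time reversal
    (backward point-source simulation, transducer placement, lens thickness
    map, forward verification with focal and electrode-clearance metrics),
    Pennes bioheat safety simulation against the ITRUSST temperature gate,
    a synthetic generator for multi-rate LFP/EEG recording sessions with
    planted beta-band effects and known ground truth, the sham-normalised
    beta-power, coherence and reaction-time contrast analysis, the
    pulse-train electrode-artefact model, and the supporting statistics
    (Lilliefors normality, paired t contrasts, Benjamini-Hochberg FDR,
    Monte Carlo power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
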