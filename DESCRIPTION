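Package: graspstim
Title: Closed-Loop Grasp-Force Encoding for Spinal Cord Stimulation Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of a closed-loop sensory
    neuroprosthesis in which prosthetic grasp force is encoded into epidural
    spinal cord stimulation amplitude. Simulates 50 Hz grasp trials against
    objects of varying size and compliance under two prosthesis-control
    schemes (contralateral data-glove proportional aperture control and EMG
    threshold-crossing constant-velocity control), implements the real-time
    signal chain (EMG envelope extraction, MVC normalization, causal
    Butterworth force filtering), maps force to stimulation amplitude by
    linear and exponential encoding schemes with hardware-limit validation,
    extracts per-trial stimulation features (onset lag, peak amplitude, rate
    of change, aperture at onset), and tests object discriminability with
    exact binomial tests, MANOVA/ANOVA with Tukey-HSD post-hoc comparisons,
    standard deviational ellipses, and a pooled-covariance nearest-centroid
    ideal observer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
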