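Package: htrcine
Title: Retrospectively Gated High-Temporal-Resolution CINE MRI Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates an ungated FLASH acquisition of a beating mouse-heart
    phantom together with its physiological event log (R-waves, respiration,
    RF line timestamps), reconstructs high-temporal-resolution CINE image
    stacks (90 frames per cardiac cycle) by retrospective k-space binning
    with respiratory and arrhythmia rejection, extracts left-ventricular
    time-volume curves, early/atrial (E/A) filling peaks and systolic
    metrics (EDV, ESV, SV, EF), and computes test-retest repeatability
    statistics (coefficient of variation, Bland-Altman repeatability
    coefficient and limits of agreement, Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
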