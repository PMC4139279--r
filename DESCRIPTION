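Package: prsafhr
Title: Phase-Rectified Signal Averaging of Fetal Heart Rate Under
    Umbilical Cord Occlusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes acceleration and deceleration capacity (AC/DC) of
    fetal beat-to-beat RR-interval series by phase-rectified signal
    averaging (PRSA) across a spectrum of anchor-filter lengths, with the
    artifact reconstruction, anchor-exclusion and quality-control rules
    used in umbilical-cord-occlusion (UCO) sheep experiments.  Includes
    exponential fitting of the heart-rate response to occlusion onset and
    release, extraction and concatenation of deceleration-free ("stable")
    intervals, nonparametric small-sample statistics (exact Wilcoxon
    signed-rank, Spearman correlation with acid-base biomarkers), and a
    seeded synthetic UCO-protocol generator so the complete analysis is
    reproducible without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
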