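Package: rebamotion
Title: Continuous REBA Ergonomic Risk Scoring from Inertial Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-wise Rapid Entire Body Assessment (REBA) scoring of
    full-body joint-angle recordings from inertial motion capture, with
    vertical load estimation from pelvic kinematics, duration-normalised
    risk-band histograms, and a nonparametric comparison battery
    (Wilcoxon-Mann-Whitney, Kruskal-Wallis, Bonferroni-Holm, Cliff's delta).
    Includes readers and writers for a reduced MVNX-style XML export and a
    tabular CSV dialect, a synthetic motion generator that scripts the three
    phases of a classical ballet training session with known ground truth,
    and an end-to-end session pipeline producing per-sequence, per-phase and
    whole-session risk summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    signal
Config/testthat/edition: 3
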