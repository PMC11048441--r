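Package: votkit
Title: Vascular Occlusion Test Analysis of Muscle NIRS and DCS Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing forearm-muscle vascular occlusion tests (VOT)
    recorded with near-infrared spectroscopy (NIRS; oxy- and deoxy-hemoglobin,
    tissue saturation index) and diffuse correlation spectroscopy (DCS; blood
    flow index). Provides cardiac-band low-pass filtering, DCS bin averaging,
    phase segmentation (baseline, occlusion, reactive hyperemia), extraction of
    the full occlusion/hyperemia parameter set (baseline means, occlusion
    slopes and extrema, relative-blood-flow floor, hyperemic peaks, slopes and
    half-time to recovery), two-group statistics (Hotelling's T-squared family
    tests, Bonferroni-adjusted pairwise comparisons with log/non-parametric
    fallbacks, Cohen's d), and a synthetic-trace generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
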