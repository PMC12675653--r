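Package: psaqc
Title: Quantification of the Pupil-Size Artifact in Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("psaqc", "developers", email = "psaqc@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying the pupil-size
    artifact (PSA) in video-based eye trackers. Generates ground-truth-known
    bright/dark fixation sessions, maps head-mounted scene-camera gaze from
    pixels to screen-centered degrees of visual angle (fiducial marker
    detection, lens undistortion, pixel-to-millimeter scaling, pinhole
    viewing-distance estimation), applies a standard cleaning chain
    (middle-75 percent trimming, 10-degree distance filter, 3-SD outlier
    filter), and computes gaze data-quality metrics (accuracy, apparent gaze
    shift, STD precision, RMS sample-to-sample, data loss) together with
    paired t tests, Bonferroni correction and Cohen's d effect sizes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
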