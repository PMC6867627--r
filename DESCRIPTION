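Package: ringlane
Title: Run-and-Rest Motility Fingerprinting for Ring Micro-Lane
    Migration Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-cell migration on ring-shaped 1D
    micro-lanes: projection of tracking coordinates onto ring geometry
    and angular unwrapping, two-state (run/rest) segmentation of
    trajectories, exponential dwell-time survival fits with 99%
    confidence intervals, and the five-parameter motility fingerprint
    (run velocity, run and rest state lifetimes, run-time fraction and
    path persistence) at single-cell and population level.  Includes a
    stochastic two-state trajectory simulator that supplies ground
    truth for validating every analysis stage, condition comparison by
    Welch t-tests and confidence-interval overlap, and Feret-diameter
    shape factors plus relative staining intensity for binary cell
    masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
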