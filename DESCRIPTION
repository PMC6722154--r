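Package: egopoint
Title: Analysis and Simulation of Egocentric Pointing Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mobile-device egocentric pointing tests of spatial
    orientation and memory. Reads and writes pointing-session JSON files of
    3D unit pointing vectors in East/North/Up coordinates, converts vectors to
    body-referenced azimuth and elevation angles, and provides the circular
    statistics used to score them: circular means and dispersions, the
    Rayleigh uniformity test, von Mises fits and two-component von Mises
    mixtures for bimodal mental-rotation errors. Computes eyes-open baselines,
    per-trial pointing errors across eyes-open, eyes-closed, real-rotation and
    mental-rotation conditions, internal-consistency and test-retest
    reliability (McGraw-Wong intraclass correlations, Cronbach's alpha),
    repeated-measures condition effects with permutation tests, and
    correlations with self-report questionnaires. A seeded generative model
    simulates whole cohorts with realistic dispersion structure, flip
    artifacts and laterality effects for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
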