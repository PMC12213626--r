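Package: retoct
Title: Quantitative Retinal OCT Analysis for Sodium-Iodate Degeneration Models
Version: 0.1.0
Authors@R: person("Visual Function", "Analytics", email = "vfa@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify retinal degeneration from optical coherence
    tomography (OCT) B-scans of the mouse eye: shortest-path (dynamic
    programming) retinal layer segmentation with median ensembling of
    segmenter variants, estimated attenuation coefficient (eAC) images,
    region-of-interest layer morphometry relative to the optic nerve head,
    Dip-ratio reflectance biomarker, vitreous particle counting, and
    time-course statistics (exponential decay fits, bootstrap R-squared,
    paired t-tests).  Includes a speckle-noise B-scan phantom generator
    with ground truth that emulates the sodium-iodate degeneration time
    course, used throughout the test suite as an oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
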