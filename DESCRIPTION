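Package: vfat1
Title: Accurate 3D Variable Flip Angle T1 Mapping of the Liver
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for accurate and precise 3D liver T1 mapping at 3T from
    variable flip angle (VFA) spoiled gradient-recalled echo (SPGR)
    acquisitions. Implements the steady-state SPGR and inversion-recovery
    signal models, extended phase graph (EPG) simulation of RF- and
    gradient-spoiled sequences with an incomplete-spoiling correction,
    double-angle B1+ mapping (3D long-TR and 2D EPI with slice-profile and
    through-slice B0-gradient corrections), dual-echo B0 mapping with phase
    unwrapping, EPI distortion correction, two-echo Dixon water-fat
    separation, B1+-corrected non-linear least squares T1 fitting, a
    Bloch-simulated MOLLI forward model with Look-Locker correction, and
    the weighted ROI summary, B1+-sensitivity and repeatability statistics
    used to validate such maps. A digital phantom generator emulates the
    vial phantom and abdomen-like acquisitions end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
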