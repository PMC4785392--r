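Package: clvtrack
Title: Quantification of Collecting Lymphatic Vessel Contractility from
    Near-Infrared Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify collecting lymphatic vessel (CLV) contractility
    from near-infrared (NIR) fluorescence time-lapse recordings. Implements
    per-frame inner-diameter tracking with a moving vessel/background
    intensity threshold applied to a vessel-bisecting line profile, automatic
    multiscale-based peak and trough detection (AMPD) on diameter or
    fluorescence traces, and the derived contractility outcome measures:
    contraction frequency, percent amplitude relative to the instantaneous
    mean, pumping score (frequency times percent amplitude), and vessel tone.
    Includes baseline-normalized treatment comparisons, a synthetic
    vessel-phantom generator with closed-form ground truth for validation,
    CSV/TIFF input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
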