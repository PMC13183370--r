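Package: vocalmap
Title: Whole-Brain Activity Mapping of Mouse Courtship Ultrasonic Vocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for double-label (activity-tagged reporter plus
    acute immediate-early-gene) whole-brain mapping of courtship ultrasonic
    vocalization (USV) in mice. Provides USV event segmentation from ultrasonic
    audio with a spectral-bandwidth rule, ROI-polygon cell-density
    quantification and double-label (reactivation) matching, dual z-score
    heatmap normalization with outlier exclusion, Pearson-correlation-based
    functional classification of brain regions, anteroposterior correlation
    profiling along the bregma axis, geometric quadrant segmentation of the
    caudoputamen, and striosome/matrix compartment quantification. A synthetic
    cohort generator with known ground truth makes every stage testable without
    raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
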