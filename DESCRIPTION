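Package: activecomm
Title: Computer-Vision-Guided Active Commutator Control and Wide-Field
    Calcium Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a computer-vision-guided active
    translating commutator for tethered neural recordings in freely
    behaving mice. Provides heading-angle accumulation from two-point
    pose streams (dot/cross-product signed deltas with confidence
    gating), threshold-triggered rotation compensation, segment-based
    translation compensation on a linear track, a rate-limited stage
    simulator with cable-twist accounting, radius-thresholded tracking
    evaluation against manual annotations, a dual-illumination
    wide-field calcium preprocessing chain (K-means channel
    segregation, outlier removal, rigid motion correction, bilinear
    binning, masked DF/F with ratiometric hemodynamic correction,
    zero-phase Chebyshev band-pass, mask-aware spatial smoothing,
    per-pixel z-scoring), peri-event bootstrap statistics with
    Bonferroni correction, and synthetic-data generators with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
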