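Package: stereoKi67
Title: Image-Analysis-Assisted Stereology for Auditing Ki67 Immunohistochemistry Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multicolor digital image analysis (DIA) markup masks of
    Ki67-stained tissue-microarray spots into editable point annotations laid
    over a systematic uniform random grid of unbiased 2D counting frames, and
    audits expert-corrected annotation files against the machine-generated
    ones. Marks are recovered from the markup raster by Excess-RGB channel
    thresholding, connected-component labeling and centroid extraction, and
    written to an ImageScope-style annotation XML dialect. The audit matches
    the machine (dD) and corrected (cD) mark sets, classifies every difference
    (label flips, false detections, nuclei undetected by the tissue-mask or
    the nuclear-segmentation component), and aggregates editing effort,
    Ki67 percentage regression and Bland-Altman agreement across a spot
    series. A fully logged synthetic spot generator provides ground-truth
    fixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    jsonlite,
    png,
    tiff,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
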