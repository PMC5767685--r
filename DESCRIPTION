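Package: personmvpa
Title: Part-Based Analysis of Whole-Person Multi-Voxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether whole-person multi-voxel fMRI response
    patterns are part-based linear combinations of face and body patterns.
    Provides a synthetic-data generator for block-design experiments under
    part-based and integrated representation scenarios, GLM beta-pattern
    estimation and condition-volume extraction, cross-run pattern similarity
    analysis with Fisher-z representational similarity matrices, convex
    face/body weight estimation by grid search, three-emotion linear SVM
    decoding with ANOVA feature selection and FDR correction, and video
    stimulus statistics (inter-frame movement, RMS contrast, mean luminance).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
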