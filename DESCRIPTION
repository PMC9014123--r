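Package: fundusfusion
Title: Joint Diabetic Macular Edema Classification and Hard-Exudate
    Detection on Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simultaneous image-level diabetic macular edema
    (DME) grading and hard-exudate (HE) lesion detection on colour fundus
    photographs. Implements multi-annotator bounding-box consensus by
    IoU matching, the one-disc-diameter geometric DME rule anchored on
    optic-disc and macula landmarks, fundus-region cropping and resizing
    with annotation transport, a shared-backbone fusion network joining a
    bi-directional feature-pyramid detection head with a three-layer
    classification head under a weighted focal/detection loss, an
    image-level detection evaluation protocol, and the accompanying
    statistics (ROC/AUC, DeLong comparison, two-proportion z-test,
    dataset profiling). A synthetic fundus-scene generator with simulated
    annotators makes the whole pipeline testable end to end at
    configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
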