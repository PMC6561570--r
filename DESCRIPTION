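Package: csannosim
Title: Simulated Citizen-Science Annotation Noise and Classifier Robustness
    for Benthic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the common error modes of citizen-science object
    detections in marine imagery (inaccurate position, inaccurate radius,
    background false positives, and empirically fitted Gaussian deviations)
    by perturbing expert gold-standard square annotations, quantifies
    annotation quality against the gold standard (valid/false-positive/
    false-negative counts, relative deviations, overlaps, fitted deviation
    models), and measures the resulting degradation of a patch classifier.
    Includes a synthetic seafloor-scene generator with exact ground truth so
    the whole pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
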