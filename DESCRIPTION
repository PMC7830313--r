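Package: slcau
Title: Sparse Locally-Coherent 3D Morphable Models for Facial Action Unit
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds sparse and locally-coherent 3D morphable face models
    (SLC-3DMM) from registered 3D scans by non-negative elastic-net
    dictionary learning over per-coordinate displacement samples, fits them
    to raw scans with an iterative closed-form regularized procedure, and
    isolates facial Action Unit (AU) deformation coefficients via a two-step
    neutral/expressive fit.  The coefficients feed a One-vs-Rest RBF-SVM AU
    classifier evaluated with leave-one-subject-out cross-validation, and
    per-AU prototype coefficients can be synthesized back onto arbitrary
    neutral faces.  Includes OBJ/PLY mesh input/output with landmark
    sidecars, landmark-guided dense correspondence by per-region
    resampling, a PCA baseline model, and a synthetic face-corpus generator
    for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
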