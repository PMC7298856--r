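Package: vectorenm
Title: Ecological Niche Modelling and Climate-Change Exposure Mapping for
    Disease Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for presence-background ecological niche
    modelling of arthropod disease vectors such as the cattle tick
    Rhipicephalus (Boophilus) microplus. Implements spatial thinning of
    occurrence records, accessible-area construction, collinearity
    filtering and candidate variable-set enumeration, a maximum-entropy
    (Maxent-class) suitability model with linear, quadratic, product,
    threshold and hinge features and L1 regularization, model selection by
    partial-ROC significance, omission rate and AICc, transfer to future
    climate scenarios with mobility-oriented parity (MOP) extrapolation
    detection, GCM ensemble agreement and change-class mapping, and
    overlay of suitability changes on livestock-abundance categories and
    zoogeographic regions. Includes a synthetic-data generator that
    emulates the statistical structure of bioclimatic layers, future
    climate ensembles, occurrence sampling and cattle-abundance fields so
    the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
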