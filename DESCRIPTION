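Package: riskgauge
Title: Absolute and Relative Performance Measures for Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes absolute discrimination measures for binary risk
    prediction models (AUC, the Lorenz-curve-based Gini and Pietra indices,
    and the scaled Brier score) alongside the relative model-comparison
    measures they are often contrasted with (NRI, continuous NRI, IDI),
    and provides a simulation engine for marker-addition experiments with
    binary, continuous and polygenic markers, including "gray-zone
    resolving" markers whose discrimination power is concentrated where a
    baseline model is uninformative.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
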