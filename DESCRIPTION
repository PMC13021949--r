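Package: ecggnn
Title: Spatial-Temporal Graph Neural Networks for 12-Lead ECG Classification and Explanation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms 12-lead electrocardiograms into spatial-temporal graphs
    (leads x time patches), trains a graph convolutional network classifier for
    diagnostic superclass and myocardial-infarction localization tasks, and
    explains predictions with learned edge and node-feature masks that maximize
    the mutual information between the masked-input and original predictions.
    Instance explanations are aggregated to cohort-level lead-importance maps
    for comparison against clinical lead-location knowledge. Includes a minimal
    WFDB format-16 reader/writer, a delay-compensated polyphase resampler, a
    synthetic 12-lead ECG cohort generator with lead-localized class signatures,
    matched-control sampling on sex and age bins, and multiclass evaluation
    metrics (weighted F1, Matthews correlation, one-vs-rest AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
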