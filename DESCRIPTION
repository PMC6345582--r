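Package: sirep
Title: Stimulus Information Representation Analysis for Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the stimulus information representation (SIR) framework
    for relating visual stimulus information, source-space neural activity, and
    perceptual decisions. Provides Bubbles aperture sampling of spatial-frequency
    decomposed images, Gaussian-copula mutual information estimators for
    continuous and mixed continuous-discrete variables, co-information
    (redundancy) among stimulus features, neural activity and behavior,
    permutation maximum-statistic family-wise error control, non-negative matrix
    factorization of mutual-information images into brain features, dynamic
    representation matrices with onset/offset wavefront analysis and
    diagnostic/nondiagnostic divergence, representational complexity over the
    extended N/M170 window, and a fully specified synthetic observer generator
    with planted ground truth so every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
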