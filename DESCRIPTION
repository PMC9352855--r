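Package: usemnet
Title: Person-Specific Directed Functional Connectivity Networks via
    Unified Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates person-specific directed functional connectivity
    networks from multivariate region-of-interest (ROI) time series using
    unified structural equation models (uSEM) with contemporaneous and
    lag-1 directed paths. Implements a two-stage data-driven model search
    in the style of group iterative multiple model estimation (GIMME):
    group-level paths supported by most of the sample are added first,
    followed by person-unique paths until standard fit indices (RMSEA,
    SRMR, CFI, NNFI) indicate good fit, with all weights estimated
    uniquely per person. Provides network complexity and subnetwork
    density metrics, descriptive and correlation summaries linking
    network metrics to hormone and behavior measures, a synthetic-data
    generator that simulates the full study design (group plus individual
    directed structure, hormone and task-performance covariates), and a
    reproducible end-to-end pipeline with delimited-text input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
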