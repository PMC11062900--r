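Package: tundresp
Title: Meta-Analysis and Spatial Upscaling of Warming Effects on Tundra
    Ecosystem Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesizing open-top-chamber warming experiments on
    tundra ecosystem respiration: standardized effect sizes (Hedges' g,
    log response ratio, raw mean differences) from plot-level flux records,
    multilevel random-effects meta-analysis fitted by restricted maximum
    likelihood with nested experiment/dataset intercepts and a
    continuous-time AR(1) structure of true effects over years,
    single-factor metaregression with omnibus moderator tests and McFadden
    pseudo-R-squared, and Monte Carlo uncertainty-propagated upscaling of a
    fitted soil-driver model across gridded total nitrogen and soil organic
    carbon data, including truncated correlated sampling, C:N bias
    correction, mixture standard deviations and uncertainty-source
    decomposition. A synthetic-data generator reproduces the hierarchical
    structure of such syntheses for validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
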