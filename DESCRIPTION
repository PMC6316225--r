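Package: violacap
Title: Host-Plant Carrying Capacity for Viola-Feeding Speyeria Butterflies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how many Speyeria pupae a site's Viola host biomass can
    support. Fits candidate parametric families (normal, log-normal, truncated
    normal, gamma, Weibull) to field measurements of leaves per plant, leaf
    area, and larval leaf-area consumption by maximum likelihood with AIC
    model selection; models per-segment violet density as a zero-inflated
    exponential mixture with a likelihood-ratio test against the pure
    exponential; and propagates the fitted distributions through a Monte
    Carlo simulation of site-level leaf area present and pupae supported,
    including a density sweep, segment-level capacity extrapolation, and a
    synthetic field-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
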