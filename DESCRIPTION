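Package: herbtrends
Title: Herbicide Use Intensity and Relative Toxicity Trend Analysis
Version: 0.1.0
Authors@R:
    person("herbtrends", "maintainers", email = "maintainers@herbtrends.invalid",
           role = c("aut", "cre"))
Description: Computes herbicide use intensity as area-treatments (total
    amount applied divided by the average application rate and the planted
    crop area) and relative mammalian toxicity as chronic and acute hazard
    quotients (amount applied per hectare divided by the 24-month rat NOEL
    or the acute oral rat LD50), from USDA-NASS-style pesticide use survey
    tables. Consolidates salt- and ester-specific ingredient labels into
    canonical active ingredients, applies the conservative 5000 mg/kg
    substitution for censored LD50 values, decomposes hazard quotients into
    per-ingredient contribution shares, and tests time trends with the
    Mann-Kendall test (exact small-sample p-values), ordinary least squares
    slopes, and Pearson correlation. Includes a synthetic survey-data
    generator with exact ground truth so the whole pipeline is testable
    without external downloads, and a command-line interface for end-to-end
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
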