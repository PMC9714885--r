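Package: profilepoll
Title: Maximum-Likelihood Profile Polling for Child Stunting Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing households of stunted under-five
    children in DHS-style household surveys by "polling": weighted empirical
    joint distributions over covariate profiles, conditional frequencies,
    winning-profile selection with coverage and edge statistics, and
    exhaustive search over k-variable covariate subsets, nationally and by
    administrative stratum. Includes stunting severity classification from
    height-for-age z-scores, weighted prevalence tables with district-level
    severity banding, univariate covariate screening, and a synthetic
    children's-recode-like data generator with planted profile effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
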