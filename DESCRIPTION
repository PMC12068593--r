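Package: amblyref
Title: Referral-Criteria Analysis for Pediatric Photorefraction Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing automated vision-screening cohorts of young
    children. Classifies per-child photorefraction readings (sphere, cylinder,
    axis, or device status codes) under six published amblyopia referral
    criteria sets, including the AAPOS 2021 age-based examination failure
    levels and four instrument referral criteria; compares referral and
    refractive-error rates across criteria with Cochran's Q and McNemar
    paired-proportion tests; stratifies results by school type with chi-square
    or Fisher exact tests; deterministically reconstructs a cohort from
    published marginal count tables; and simulates realistic screening cohorts
    with correlated interocular refraction for property testing and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
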