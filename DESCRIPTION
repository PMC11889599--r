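Package: platformsim
Title: Operating Characteristics of Platform Trials with Shared Concurrent
    Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Monte Carlo simulation of stand-alone, multi-arm, and platform
    clinical trials that compare several drugs against a shared placebo
    control on a binary mortality endpoint. Supports equal and dynamic k:1
    unequal randomization, staggered (monthly or uniform-random) addition of
    drug arms, monthly Poisson accrual, concurrent-control-only two-by-two
    testing (Pearson chi-squared with a Fisher exact fallback), closed-form
    two-proportion sample-size and power calculations, aggregation of
    replicate decisions into operating characteristics (type I error,
    group-specific and overall power, placebo sample sizes, Monte Carlo
    standard errors), and regression of the unequal-versus-equal power gain
    on the placebo-group size increase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
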