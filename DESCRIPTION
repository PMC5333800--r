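Package: litpower
Title: Power, Effect-Size and False-Report-Probability Surveys of a
    Statistical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for large-scale surveys of statistical power in a
    published literature. Extracts full t-test records (degrees of freedom,
    t, p, Cohen's d) from article plain text with a two-phase parser,
    converts t statistics to standardized effect sizes under a
    degrees-of-freedom-conditional mixture of one-sample/matched and
    two-sample tests, computes two-sided power from the noncentral t
    distribution, and models the false report probability (FRP) of
    significant findings as a function of prestudy H0:H1 odds and reporting
    bias, including its expectation over the empirical (df, effect size)
    distribution. A synthetic-literature simulator with selective
    publication, bias flipping and text rendering in common reporting
    dialects makes every stage of the pipeline verifiable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
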