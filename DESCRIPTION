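Package: extractopt
Title: Response-Surface and Neural-Network Optimization of Extraction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for design-of-experiments optimization of natural-product
    extraction processes. Builds central composite rotatable designs (CCRD),
    fits full second-order response-surface models with complete ANOVA
    diagnostics (partial sums of squares, lack of fit versus pure error,
    PRESS, coefficient of variation), locates surface optima by ridge
    analysis and box-constrained multi-start maximization, trains a
    single-hidden-layer perceptron surrogate by full-batch quasi-Newton
    minimization of mean squared error, and compares the two surrogates with
    R-squared, root mean square error and absolute average deviation. Ships
    a worked ultrasound-assisted chlorogenic-acid extraction data set and a
    synthetic CCRD generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
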