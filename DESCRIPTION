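Package: moralmpt
Title: Multinomial Processing Tree Analysis of Moral Dilemma Judgments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the analysis of moral-dilemma judgment batteries in
    which each scenario varies a moral norm (proscriptive or prescriptive)
    and a benefit-to-cost ratio. Implements the CNI multinomial processing
    tree, which decomposes binary action/inaction judgments into sensitivity
    to consequences (C), sensitivity to moral norms (N), and a generalized
    preference for inaction (I), with maximum-likelihood estimation, G-squared
    goodness of fit, Wald confidence intervals, and likelihood-ratio tests for
    parameter equality across groups and point hypotheses. Also provides the
    process-dissociation U/D decomposition, traditional dilemma scoring,
    Levenson Self-Report Psychopathy (LSRP) scale scoring with extreme-group
    assignment, supporting statistics (pooled t, Cohen's d, Cronbach's alpha),
    and a seeded synthetic-cohort generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
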