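Package: burnoutbn
Title: Bayesian Network Analysis of Burnout, Resilience, and Workplace Safety Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the association between job-burnout dimensions
    (emotional exhaustion, depersonalization, reduced personal accomplishment),
    psychological resilience, and unsafe workplace behaviors (poor safety
    compliance and poor safety participation) with a discrete Bayesian network.
    Provides psychometric scoring for the Maslach Burnout Inventory, the
    Connor-Davidson Resilience Scale, and a two-dimension safety-behavior
    questionnaire; median-split dichotomization into binary model variables;
    exact inference by variable elimination; conditional-probability-table
    estimation by crosstab maximum likelihood and by expectation-maximization
    on records with missing cells; hard-evidence (100%) univariate and
    multivariate sensitivity analysis, Delta-p, and distance-based arc
    strength-of-influence; k-fold cross-validation with ROC analysis; and a
    synthetic survey generator so the whole pipeline is testable without
    access to confidential respondent data. Networks can be exchanged as
    JSON, YAML, or GeNIe XDSL files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
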