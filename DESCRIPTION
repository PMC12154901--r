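Package: ptoswf
Title: Person Trade-Off Elicitation and Health-Related Social Welfare
    Function Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying distributive preferences over health gains
    with the person trade-off (PTO) technique. Provides the five-task PTO
    battery trading the size of individual health gains against the number
    of beneficiaries, a three-step adaptive elicitation engine (rationality
    gate, bisection ladder, bounded open-ended finish), a seeded synthetic
    respondent generator with latent social-welfare parameters and
    behavioural archetypes, classification of responses into five
    distributive-preference types, hypothesis tests with Bonferroni
    correction, test-retest reliability via the intraclass correlation
    coefficient, and estimation of the health-gain threshold at which
    preferences flip from diffusion to concentration by fitting the
    social welfare function u(t) = a1*exp(b*t)*t^a by ordinary least
    squares with a respondent-level percentile bootstrap for the
    threshold's confidence interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
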