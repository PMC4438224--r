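Package: perinatalcosts
Title: Short-Term Cost Modeling of Gestational Diabetes, Maternal
    Overweight, and Macrosomia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic framework for estimating the short-term
    (pregnancy and delivery) healthcare costs of gestational diabetes
    mellitus (GDM), maternal overweight, and related fetal macrosomia from
    a payer perspective.  Provides a generic decision-tree engine with
    expected-value rollback and a path-enumeration oracle, a discrete-time
    Markov cohort engine for post-delivery follow-up, per-case expected
    cost breakdowns (mother / child / total), national budget-impact
    analysis, and one-way deterministic sensitivity analysis with tornado
    ranking.  Ships a fully parameterized US 2011 configuration
    (perinatal complication probabilities, unit costs, treatment odds
    ratios, population demographics) plus a validated reader for
    user-supplied YAML/JSON configurations, and a command-line interface
    for reproducible report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
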