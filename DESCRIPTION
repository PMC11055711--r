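Package: cogpheno
Title: Cognitive Phenotyping and Longitudinal Change Analysis for
    Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for regression-based normative scoring of an extended
    Brief Repeatable Battery of Neuropsychological tests, composition of
    four a-priori cognitive domains (information processing speed, memory,
    executive functioning/working memory, attention), classification of
    people with multiple sclerosis into preserved, isolated and
    multi-domain cognitive-impairment phenotypes, reliable-change-index
    based longitudinal transition analysis, and MRI-predictor regression
    modelling with collinearity screening and forward selection.  Includes
    a synthetic-cohort generator that emulates a healthy-control normative
    sample and a patient cohort with group-structured cognitive and MRI
    effects, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    nortest,
    withr,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
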