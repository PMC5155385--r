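Package: tempdx
Title: Temporal Bayesian Differential Diagnosis and Decision-Support Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A diagnostic decision-support engine that ranks diseases by
    Bayesian pattern matching against a curated disease-finding knowledge
    base with age-dependent incidence, finding frequencies, onset and
    disappearance age intervals, pertinent negatives and disease acuity of
    onset. Includes value-of-information ranking of unobserved findings and
    test bundles, a synthetic knowledge-base and patient simulator with
    user-input-error corruption modes, and an evaluation framework for
    before/after decision-support studies: diagnostic error and relevance
    metrics, change classification, grouped aggregation tables, and a
    logistic generalized estimating equations analysis for clustered binary
    outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'knowledge_base.R'
    'temporal_bayes.R'
    'suggestion.R'
    'synthetic.R'
    'evaluation.R'
    'fixtures.R'
    'gee.R'
    'cli.R'
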