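Package: catlr
Title: Category-Oriented Likelihood Ratios for Diagnostic Probability Revision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evidence-based diagnostic reasoning with likelihood
    ratios (LRs). Implements odds/probability algebra and sequential Bayesian
    revision of disease probabilities, the category-oriented likelihood ratio
    (how much more likely a clinical finding is among patients with any disease
    of a category versus patients with a disease outside it), selection of the
    most discriminative LR within groups of statistically dependent findings,
    expert scheme trees that route a patient through branching points while
    revising category probabilities, and a virtual-cohort simulator with an
    exact enumeration-Bayes oracle for deriving, estimating and validating
    category-oriented LRs. Ships transcriptions of published diagnostic
    accuracy and prevalence tables for urinary tract infection and non-acute
    abdominal pain as worked examples, and a command-line interface for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
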