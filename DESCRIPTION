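Package: metaflex
Title: Metacognitive Efficiency and Cognitive Flexibility from
    Confidence-Rated Decisions and Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating metacognitive sensitivity (meta-d'),
    metacognitive efficiency (M-ratio) and metacognitive bias from
    confidence-rated two-choice decisions under the type-2 signal detection
    theory model, by subject-level maximum likelihood and by hierarchical
    Bayesian MCMC; for scoring learning and re-learning speed (cognitive
    flexibility) in a rule-reversal trading game with a run-based learning
    criterion; for generating synthetic cohorts with tunable group effects
    and a copula-coupled confidence-flexibility association; and for the
    factorial/mixed ANOVA and (partial) Spearman correlation inference layer
    that ties the two task batteries together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
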