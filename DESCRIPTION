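Package: tmtscreen
Title: TMT Proteomics Screening, Feature Selection and Survival Cutpoint Pipeline
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a discovery proteomics screening
    chain for isobaric-label (TMT) experiments: peptide-level relative
    quantification and median rollup to proteins, fold-change plus t-test
    differential screening, recursive feature elimination with a linear
    margin ranker and a random forest ranker, concordance of discovery fold
    changes with a targeted validation panel, and maximally selected
    log-rank cutpoint dichotomization of a continuous marker in a
    right-censored survival cohort.  A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
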