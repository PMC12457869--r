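Package: emapsych
Title: Psychometric Evaluation of Momentary Versus Retrospective Measures of Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating whether ecological momentary assessment
    (EMA) measures of rumination can stand in for conventional retrospective
    questionnaires when the quantity of interest is change during an
    intervention trial. Implements reliability of residualized and raw
    change scores, random split-half reliability of EMA means and
    person-level OLS slopes with Spearman-Brown adjustment, multilevel-model
    slope reliability, windowed EMA means and compliance summaries,
    growth-model effect sizes, ANCOVA-style group comparisons, and
    criterion-validity models predicting depression improvement.  A
    synthetic trial generator with known ground truth makes the entire
    four-criterion pipeline testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
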