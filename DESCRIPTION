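Package: resperr
Title: Response Error Scores, Worst-Performance and Task-Complexity
    Analysis for Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cognitive-ability information from response patterns in
    multi-item ordinal questionnaires. Fits unidimensional graded response
    models per scale, computes expected-a-posteriori trait estimates and
    item-level response-error scores, codes ten linguistic item-complexity
    indicators from item text, runs a worst-performance-rule decile analysis
    with an omnibus Wald test on dependent correlations, and estimates
    moderated and reparameterized random-slope mixed models (including
    latent-variable variants) of the ability-by-complexity interaction. A
    synthetic-data generator emulating the target study design makes the
    whole pipeline testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
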