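Package: lesionette
Title: Simulated Neural Damage in Recurrent Connectionist Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and lesions two classic connectionist models of
    neuropsychological deficits: a recurrent hub-and-spoke auto-associator
    of semantic knowledge (picture naming of animals versus artefacts) and
    a simple recurrent network of routine sequential action (coffee and tea
    preparation). Provides synthetic binary-feature pattern generators with
    calibrated category statistics, five parameterised damage operators
    (connection severing, weight perturbation, unit ablation, weight
    scaling, activation noise), and the behavioural analyses used to compare
    them: domain-specific naming-accuracy curves with area-between-curves
    confidence intervals, attractor-density and weight-distribution
    summaries, sequential-action error taxonomies, and survival curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
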