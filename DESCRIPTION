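Package: sinkcod
Title: Underlying Cause-of-Death Inference from ICD-10 Cause-of-Death Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic inference of the underlying cause-of-death from the
    ordered ICD-10 cause-of-death chain on a death certificate. Implements
    the "sink" algorithm: fit conditional death-cause proportions (CDCP)
    stratified by age group and gender from labeled death records, then
    select the chain or history candidate with the largest CDCP, with a
    short-circuit rule for external (injury) direct causes. Also provides
    regional death-cause proportions (RDCP), additive smoothing, a raw and a
    log2-transformed estimator variant, k-fold cross-validation with
    per-cause precision/recall/F1, naive Bayes and k-nearest-neighbour
    reference baselines, and a seeded synthetic death-record generator so
    the whole pipeline is testable without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
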