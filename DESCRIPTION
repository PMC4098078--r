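Package: restfc
Title: Seed-Based Resting-State Functional Connectivity with Permutation Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seed-based resting-state functional connectivity (rFC) pipeline
    for block-design fMRI studies: selection of interspersed baseline (rest)
    volumes, nuisance regression with a 30-regressor confound model and
    zero-phase band-pass filtering, spherical seed definition in MNI space with
    first-eigenvariate extraction, per-subject Fisher-Z connectivity matrices,
    age/sex adjustment, a Monte-Carlo median permutation test for group
    differences with effect-size gating, Spearman correlation of connectivity
    with behavioral creativity scores, and a synthetic two-group BOLD cohort
    generator with planted covariance effects and coupled behavioral scores for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
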