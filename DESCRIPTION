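Package: kmereg
Title: Kernel Mean Embedding Regression for Trait Prediction from EEG Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts scalar subject traits (such as chronological age) from
    single-channel EEG power spectra by reinterpreting each unit-mass
    spectrum as a probability distribution over frequency. Distances between
    subjects are empirical maximum mean discrepancies (MMD) between these
    distributions; a radial basis function kernel on the distance matrix
    feeds a dual-form ridge regression (kernel mean embedding regression,
    KMER). Includes ridge regression and kernel ridge regression baselines,
    a site-grouped nested cross-validation protocol that never splits
    acquisition sites across folds, brain-age delta computation with
    post-hoc bias correction, paired sign-flip permutation tests, and a
    seeded synthetic-cohort generator with age-dependent spectral structure,
    site-level prior shift and sex-dependent ageing slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
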