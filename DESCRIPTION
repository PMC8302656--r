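Package: ecgkelm
Title: Evolutionary Hybrid Classification of ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying electrocardiogram (ECG) fragments with an
    evolutionary hybrid classifier: class-imbalance correction by random
    oversampling, random undersampling, or importance resampling; wavelet
    denoising with a Daubechies filter bank plus moving-average baseline
    correction; feature extraction by concatenated second-, third-, and
    fourth-order cumulant slices over a symmetric lag range; a kernel extreme
    learning machine (KELM) trained in closed form; and a genetic algorithm
    that tunes the maximum cumulant lag, the KELM regularization coefficient,
    and the kernel parameter against classification error rate. A synthetic
    ECG generator with controlled morphology, noise, and class imbalance makes
    every stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
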