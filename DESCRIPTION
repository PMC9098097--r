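Package: ftirlung
Title: Discrimination of Lung Tumors from ATR-FTIR Spectra with Neural
    Networks and Classical Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the diagnostic classification of attenuated total
    reflection Fourier-transform infrared (ATR-FTIR) absorbance spectra of
    lung biopsies into benign and malignant classes.  Provides spectral
    preprocessing (rubber-band baseline correction, per-spectrum peak and
    z-score normalisation, robust outlier screening), a synthetic spectrum
    generator parameterised by the nine fingerprint-region absorption bands
    of lung tissue, peak statistics with Mann-Whitney comparisons, principal
    component analysis, six from-scratch classical classifiers (LDA, linear
    SVM with Platt calibration, logistic regression, CART decision tree,
    random forest, Bernoulli naive Bayes), self-normalising (SELU) neural
    networks in three families (feed-forward, partitioned-input recurrent,
    1-D convolutional) trained with AdaGrad, a genetic-algorithm
    hyperparameter tuner, a stratified repeated train/validation/test
    evaluation protocol with six diagnostic metrics, and a pseudo-clinical
    second-opinion procedure for diagnostically discordant samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
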