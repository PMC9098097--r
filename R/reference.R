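#' Published benchmark performance of the original study cohort
#'
#' The mean and standard deviation (percent) of the six diagnostic metrics
#' for all eleven models, as reported for the original 118-spectrum patient
#' cohort.  The patient spectra themselves are not publicly deposited, so
#' these values cannot be recomputed here; they are shipped as reference
#' inputs for arithmetic cross-checks (e.g. the published network-vs-SVM
#' mean differences are exact differences of these means) and for comparing
#' synthetic-data results against the original scale.
#'
#' @return Tibble with columns `model`, `metric`, `mean`, `sd` (percent).
#' @export
reference_performance <- function() {
  models <- c("fnn2", "fnn4", "fnn8", "rnn", "cnn",
              "dt", "rf", "nb", "lda", "lr", "svm")
  metrics <- c("AUC", "ACC", "PPV", "NPV", "SR", "RR")
  mean_ <- c(
    92.41, 92.85, 92.77, 90.40, 92.28, 78.93, 92.15, 77.91, 62.92, 82.16, 99.38,
    98.41, 98.39, 97.61, 95.98, 98.45, 77.58, 85.87, 75.13, 65.45, 72.19, 94.38,
    94.92, 96.03, 96.48, 90.91, 96.62, 73.95, 83.55, 64.65, 59.54, 65.25, 93.85,
    92.79, 93.57, 93.22, 94.03, 90.50, 80.11, 87.60, 82.21, 70.25, 94.89, 94.57,
    94.60, 94.67, 95.30, 86.63, 96.01, 84.36, 90.78, 79.79, 69.08, 74.97, 96.75,
    89.84, 90.88, 90.10, 92.87, 89.21, 73.35, 83.74, 71.10, 62.13, 64.49, 94.46)
  sd_ <- c(
    10.28, 9.98, 9.62, 11.62, 7.36, 19.87, 13.79, 21.22, 13.44, 19.84, 1.97,
    4.07, 3.57, 4.91, 6.25, 1.72, 16.91, 15.11, 19.14, 14.60, 18.68, 9.69,
    9.49, 8.63, 8.01, 11.99, 2.30, 30.28, 26.14, 33.42, 20.84, 36.13, 14.92,
    11.95, 11.28, 10.75, 9.26, 11.92, 21.98, 18.36, 22.01, 15.13, 30.57, 12.11,
    11.41, 11.57, 10.64, 17.58, 3.09, 18.04, 14.34, 18.68, 14.50, 25.98, 8.03,
    16.36, 16.13, 15.66, 13.18, 12.93, 28.25, 24.06, 33.83, 17.14, 35.74, 12.64)
  tibble::tibble(model = rep(models, times = length(metrics)),
                 metric = rep(metrics, each = length(models)),
                 mean = mean_, sd = sd_)
}
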