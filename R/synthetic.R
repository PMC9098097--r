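#' The nine-band model of lung-tissue fingerprint spectra
#'
#' Default parameterisation of the synthetic generator: the nine absorption
#' bands identified in the fingerprint region of lung biopsies, with
#' class-specific peak positions and the mean +- SD of the peak-normalised
#' absorbance at each position for malignant (n = 53) and benign (n = 65)
#' samples.  Band shapes are Gaussian with a common width (SD, cm^-1);
#' the tabulated source data carry no width information, so the default
#' (12 cm^-1) is chosen to keep adjacent bands resolvable on the 462-point
#' grid.  Amplitude draws are truncated at zero; the glycogen (1051/1030)
#' and phosphorylated-protein (880/878) band amplitudes are positively
#' correlated (default 0.5), mirroring their observed covariation.
#'
#' @param bands tibble with columns `pos_malignant`, `mean_malignant`,
#'   `sd_malignant`, `pos_benign`, `mean_benign`, `sd_benign`; defaults to
#'   the nine lung-tissue bands.
#' @param width common Gaussian band SD in cm^-1.
#' @param baseline_amplitude maximum magnitude of the random linear drift
#'   added to each spectrum (absorbance units).
#' @param noise_sd SD of the additive white noise (absorbance units).
#' @param amp_correlation correlation between the glycogen and
#'   phosphorylated-protein band amplitudes.
#' @return A list of class `band_model`.
#' @export
band_model <- function(bands = lung_bands(), width = 12,
                       baseline_amplitude = 0.05, noise_sd = 0.01,
                       amp_correlation = 0.5) {
  stopifnot(width > 0, baseline_amplitude >= 0, noise_sd >= 0,
            abs(amp_correlation) < 1)
  stopifnot(all(bands$sd_malignant >= 0), all(bands$sd_benign >= 0))
  structure(list(bands = bands, width = width,
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd, amp_correlation = amp_correlation),
            class = "band_model")
}

#' @rdname band_model
#' @export
lung_bands <- function() {
  tibble::tribble(
    ~pos_malignant, ~mean_malignant, ~sd_malignant,
    ~pos_benign, ~mean_benign, ~sd_benign, ~assignment,
    1636, 0.9605, 0.0856, 1638, 0.9885, 0.0139, "amide I, protein",
    1537, 0.7884, 0.0898, 1535, 0.8585, 0.0491, "amide II, protein",
    1452, 0.3659, 0.0687, 1452, 0.3714, 0.0510, "lipids",
    1401, 0.3244, 0.0694, 1397, 0.3480, 0.0542, "lipids",
    1314, 0.1334, 0.0582, 1312, 0.1711, 0.0591, NA,
    1236, 0.1650, 0.0766, 1236, 0.1921, 0.0775, "DNA, RNA, phospholipids",
    1160, 0.0467, 0.0343, 1160, 0.0506, 0.0475, "carbohydrates",
    1051, 0.3131, 0.1274, 1030, 0.1716, 0.0875, "glycogen",
    880, 0.5786, 0.3124, 878, 0.2595, 0.1665, "phosphorylated protein"
  )
}

band_params <- function(model, label) {
  b <- model$bands
  if (label == "malignant") {
    list(pos = b$pos_malignant, mean = b$mean_malignant, sd = b$sd_malignant)
  } else {
    list(pos = b$pos_benign, mean = b$mean_benign, sd = b$sd_benign)
  }
}

# correlated, zero-truncated amplitude draws for one spectrum
draw_amplitudes <- function(p, rho, cor_idx) {
  k <- length(p$mean)
  repeat {
    z <- stats::rnorm(k)
    if (!is.null(cor_idx) && rho != 0) {
      z[cor_idx[2]] <- rho * z[cor_idx[1]] + sqrt(1 - rho^2) * z[cor_idx[2]]
    }
    a <- p$mean + p$sd * z
    if (all(a >= 0 | p$sd == 0)) return(pmax(a, 0))
  }
}

#' Simulate a single labelled spectrum
#'
#' The absorbance at wavenumber `w` is a sum of Gaussian bands
#' `A_b * exp(-(w - pos_b)^2 / (2 width^2))` with class-conditional random
#' amplitudes, plus a gentle random linear drift of magnitude at most
#' `baseline_amplitude`, plus white noise; the result is clipped at zero.
#' Uses the current R random stream; seed it for reproducibility.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param model a [band_model()].
#' @param grid wavenumber vector (must cover the band positions).
#' @param amplitude_scale multiplier on all band amplitudes (used to inject
#'   deviant spectra).
#' @return Numeric absorbance vector aligned to `grid`.
#' @export
simulate_spectrum <- function(label, model = band_model(),
                              grid = default_grid(), amplitude_scale = 1) {
  p <- band_params(model, label)
  if (min(p$pos) < min(grid) || max(p$pos) > max(grid)) {
    stop("grid does not cover all band positions", call. = FALSE)
  }
  cor_idx <- cor_band_indices(model)
  a <- draw_amplitudes(p, model$amp_correlation, cor_idx) * amplitude_scale
  y <- gaussian_mixture(grid, p$pos, a, model$width)
  if (model$baseline_amplitude > 0) {
    tt <- (grid - min(grid)) / (max(grid) - min(grid))
    b0 <- stats::runif(1, 0, model$baseline_amplitude / 2)
    b1 <- stats::runif(1, -model$baseline_amplitude / 2,
                       model$baseline_amplitude / 2)
    y <- y + b0 + b1 * tt
  }
  if (model$noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, model$noise_sd)
  pmax(y, 0)
}

cor_band_indices <- function(model) {
  i <- which(model$bands$pos_malignant == 1051)
  j <- which(model$bands$pos_malignant == 880)
  if (length(i) == 1 && length(j) == 1) c(i, j) else NULL
}

gaussian_mixture <- function(grid, pos, amp, width) {
  drop(exp(-outer(grid, pos, "-")^2 / (2 * width^2)) %*% amp)
}

#' Noise-free class template spectrum
#'
#' The deterministic spectrum obtained with all amplitude SDs, drift and
#' noise set to zero: each band at exactly its class mean amplitude.
#'
#' @inheritParams simulate_spectrum
#' @return Numeric absorbance vector aligned to `grid`.
#' @export
class_template <- function(label, model = band_model(),
                           grid = default_grid()) {
  p <- band_params(model, label)
  gaussian_mixture(grid, p$pos, p$mean, model$width)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_malignant + n_benign` typical spectra (the study cohort default
#' is 56 malignant / 66 benign), plus optionally `n_outliers` extra deviant
#' spectra whose band amplitudes are multiplied by `outlier_scale`.  The
#' default outlier labelling is 3 malignant per 1 benign, the composition of
#' the four spectra removed from the study cohort (122 -> 118).  Fully
#' reproducible from `seed`.
#'
#' @param n_malignant,n_benign counts of typical spectra per class.
#' @param model a [band_model()].
#' @param grid wavenumber vector.
#' @param seed integer seed; `NULL` uses the current random stream.
#' @param n_outliers number of extra deviant spectra.
#' @param outlier_labels labels of the deviant spectra (recycled).
#' @param outlier_scale amplitude multiplier for deviant spectra.
#' @return An [ftir_dataset()]; outlier ids are prefixed `"OUT"` and listed
#'   in the provenance attribute.
#' @export
#' @examples
#' d <- simulate_cohort(seed = 1)
#' class_counts(d)
simulate_cohort <- function(n_malignant = 56, n_benign = 66,
                            model = band_model(), grid = default_grid(),
                            seed = NULL, n_outliers = 0,
                            outlier_labels = c("malignant", "malignant",
                                               "malignant", "benign"),
                            outlier_scale = 5) {
  if (!is.null(seed)) set.seed(seed)
  labels <- c(rep("malignant", n_malignant), rep("benign", n_benign))
  ids <- c(sprintf("MLB%03d", seq_len(n_malignant)),
           sprintf("NMLB%03d", seq_len(n_benign)))
  scale <- rep(1, length(labels))
  if (n_outliers > 0) {
    out_lab <- rep_len(outlier_labels, n_outliers)
    labels <- c(labels, out_lab)
    ids <- c(ids, sprintf("OUT%03d", seq_len(n_outliers)))
    scale <- c(scale, rep(outlier_scale, n_outliers))
  }
  m <- matrix(0, length(labels), length(grid))
  for (i in seq_along(labels)) {
    m[i, ] <- simulate_spectrum(labels[i], model, grid,
                                amplitude_scale = scale[i])
  }
  ftir_dataset(m, grid, ids = ids, labels = labels,
               provenance = c(sprintf(
                 "synthetic cohort: %d malignant, %d benign, %d outliers",
                 n_malignant, n_benign, n_outliers),
                 if (n_outliers > 0)
                   paste("outlier ids:", paste(
                     sprintf("OUT%03d", seq_len(n_outliers)), collapse = " "))))
}

#' Concordant/discordant fixture for the pseudo-clinical procedure
#'
#' Emulates the second-opinion setting: a concordant set of 94 spectra
#' (42 malignant, 52 benign) drawn at the standard class effect sizes, and a
#' discordant set of 24 (11 malignant, 13 benign) whose band parameters are
#' shifted a fraction `ambiguity` of the way toward the opposite class, to
#' mimic diagnostically ambiguous tissue.  True labels are retained.
#'
#' @param seed integer seed.
#' @param model a [band_model()].
#' @param grid wavenumber vector.
#' @param ambiguity fraction in \[0, 1\]; 0.5 moves the discordant class
#'   means halfway toward the opposite class.
#' @param n_concordant,n_discordant named counts per class.
#' @return List with `concordant` and `discordant` [ftir_dataset()]s.
#' @export
simulate_pseudo_clinical <- function(seed = NULL, model = band_model(),
                                     grid = default_grid(), ambiguity = 0.5,
                                     n_concordant = c(malignant = 42,
                                                      benign = 52),
                                     n_discordant = c(malignant = 11,
                                                      benign = 13)) {
  if (!is.null(seed)) set.seed(seed)
  concordant <- simulate_cohort(n_concordant[["malignant"]],
                                n_concordant[["benign"]], model, grid)
  amb <- ambiguous_model(model, ambiguity)
  discordant <- simulate_cohort(n_discordant[["malignant"]],
                                n_discordant[["benign"]], amb, grid)
  discordant$id <- sub("^MLB", "DMLB", discordant$id)
  discordant$id <- sub("^NMLB", "DNMLB", discordant$id)
  list(concordant = concordant, discordant = discordant)
}

# blend each class's band means/SDs toward the opposite class
ambiguous_model <- function(model, ambiguity) {
  b <- model$bands
  mix <- function(own, other) (1 - ambiguity) * own + ambiguity * other
  b2 <- b
  b2$mean_malignant <- mix(b$mean_malignant, b$mean_benign)
  b2$sd_malignant <- mix(b$sd_malignant, b$sd_benign)
  b2$mean_benign <- mix(b$mean_benign, b$mean_malignant)
  b2$sd_benign <- mix(b$sd_benign, b$sd_malignant)
  model$bands <- b2
  model
}

#' A class-identical ("null") band model
#'
#' Both classes share the benign band parameters, so labels carry no signal;
#' any downstream classifier's expected AUC is 0.5.  Used for calibration
#' checks.
#'
#' @inheritParams band_model
#' @return A [band_model()].
#' @export
null_band_model <- function(width = 12, baseline_amplitude = 0.05,
                            noise_sd = 0.01) {
  b <- lung_bands()
  b$pos_malignant <- b$pos_benign
  b$mean_malignant <- b$mean_benign
  b$sd_malignant <- b$sd_benign
  band_model(b, width = width, baseline_amplitude = baseline_amplitude,
             noise_sd = noise_sd)
}
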