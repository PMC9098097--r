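#' Pointwise median spectrum of a class
#'
#' @param data an [ftir_dataset()].
#' @param label class whose median spectrum to compute.
#' @return Numeric vector aligned to the dataset grid.
#' @export
median_spectrum <- function(data, label) {
  ix <- which(data$label == label)
  if (!length(ix)) stop("no spectra with label '", label, "'", call. = FALSE)
  apply(spectra_matrix(data)[ix, , drop = FALSE], 2, stats::median)
}

#' Prominence-based peak detection
#'
#' Finds local maxima of a spectrum and keeps those whose topographic
#' prominence (height above the higher of the two key saddles separating the
#' peak from taller terrain, with the series ends acting as open borders)
#' reaches `min_prominence`.  This operationalises visual peak picking on a
#' normalised median spectrum.
#'
#' @param x numeric absorbance vector, or an `ftir_dataset` row is not
#'   accepted — pass the vector and its grid.
#' @param w wavenumber vector aligned to `x` (defaults to indices).
#' @param min_prominence minimum prominence, in the units of `x`.
#' @return Tibble with columns `wavenumber`, `height`, `prominence`, ordered
#'   by descending wavenumber.
#' @export
detect_peaks <- function(x, w = NULL, min_prominence = 0.02) {
  n <- length(x)
  if (is.null(w)) w <- seq_len(n)
  ord <- order(w)      # ascending axis for neighbour logic
  y <- x[ord]; t <- w[ord]
  is_peak <- which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && y[i] > y[i - 1] && y[i] >= y[i + 1] &&
      # plateau rule: must eventually drop on the right before rising
      local({
        j <- i
        while (j < n && y[j + 1] == y[i]) j <- j + 1
        j == n || y[j + 1] < y[i]
      })
  }, logical(1)))
  prom <- vapply(is_peak, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence
  out <- tibble::tibble(wavenumber = t[is_peak[keep]],
                        height = y[is_peak[keep]],
                        prominence = prom[keep])
  dplyr::arrange(out, dplyr::desc(.data$wavenumber))
}

# topographic prominence of the local maximum at index i of series y
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- Inf
  j <- i - 1
  while (j >= 1 && y[j] <= y[i]) { left_min <- min(left_min, y[j]); j <- j - 1 }
  right_min <- Inf
  j <- i + 1
  while (j <= n && y[j] <= y[i]) { right_min <- min(right_min, y[j]); j <- j + 1 }
  # a side that reaches the series end without meeting higher terrain does not
  # bound the prominence unless both do (isolated summit: use the lower side)
  lm <- if (is.finite(left_min)) left_min else -Inf
  rm <- if (is.finite(right_min)) right_min else -Inf
  base <- max(lm, rm)
  if (!is.finite(base)) base <- min(y)
  y[i] - base
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum comparison of two independent samples with midrank tie handling.
#' For groups of at most `exact_max` observations each the two-tailed
#' p-value is computed by complete enumeration of all assignments of the
#' pooled values to the two groups (a permutation distribution, exact under
#' ties as well); for larger groups the normal approximation with the tie
#' correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max largest per-group size for exact enumeration.
#' @return List with `U` (statistic for the first sample) and `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                          # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = min(p, 1))
}

#' Wrapper for the Shapiro-Wilk normality test
#'
#' Gates the choice between parametric and rank-based comparison of peak
#' absorbances.  Delegates to [stats::shapiro.test()] (Royston's algorithm).
#'
#' @param x numeric vector, 3 <= length <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Band table: class peak pairing and Mann-Whitney comparison
#'
#' Reproduces the band-table analysis: detect peaks on each class's median
#' spectrum (spectra should be peak-normalised first), pair nearest
#' malignant/benign peaks within `pairing_tolerance`, read every sample's
#' absorbance at its own class's peak position, and compare the two classes
#' with the two-tailed Mann-Whitney U test.  A peak with no partner within
#' tolerance is reported as an unpaired row (NA positions for the other
#' class).
#'
#' @param data an [ftir_dataset()] containing both classes.
#' @param min_prominence passed to [detect_peaks()].
#' @param pairing_tolerance maximum |position difference| in cm^-1 for
#'   pairing (the largest tabulated offset between class positions of the
#'   same band is 21 cm^-1).
#' @return Tibble ordered by descending wavenumber with columns
#'   `pos_malignant`, `pos_benign`, `mean_malignant`, `sd_malignant`,
#'   `mean_benign`, `sd_benign`, `p_value`, `significant`.
#' @export
build_peak_table <- function(data, min_prominence = 0.02,
                             pairing_tolerance = 25) {
  w <- wavenumbers(data)
  med_m <- median_spectrum(data, "malignant")
  med_b <- median_spectrum(data, "benign")
  pk_m <- detect_peaks(med_m, w, min_prominence)$wavenumber
  pk_b <- detect_peaks(med_b, w, min_prominence)$wavenumber
  used_b <- logical(length(pk_b))
  rows <- purrr::map(pk_m, function(pm) {
    free <- which(!used_b & abs(pk_b - pm) <= pairing_tolerance)
    if (length(free)) {
      j <- free[which.min(abs(pk_b[free] - pm))]
      used_b[j] <<- TRUE
      c(pm, pk_b[j])
    } else c(pm, NA_real_)
  })
  rows <- c(rows, purrr::map(pk_b[!used_b], function(pb) c(NA_real_, pb)))
  m <- spectra_matrix(data)
  im <- data$label == "malignant"
  ib <- data$label == "benign"
  tab <- purrr::map_dfr(rows, function(pr) {
    am <- if (!is.na(pr[1])) m[im, which.min(abs(w - pr[1]))] else NULL
    ab <- if (!is.na(pr[2])) m[ib, which.min(abs(w - pr[2]))] else NULL
    # each class read at its own peak position; unpaired rows read the
    # available position for both classes so a comparison is still possible
    if (is.null(am)) am <- m[im, which.min(abs(w - pr[2]))]
    if (is.null(ab)) ab <- m[ib, which.min(abs(w - pr[1]))]
    p <- mann_whitney_u(am, ab)$p
    tibble::tibble(pos_malignant = pr[1], pos_benign = pr[2],
                   mean_malignant = mean(am), sd_malignant = stats::sd(am),
                   mean_benign = mean(ab), sd_benign = stats::sd(ab),
                   p_value = p, significant = p < 0.05)
  })
  dplyr::arrange(tab, dplyr::desc(pmin(.data$pos_malignant,
                                       .data$pos_benign, na.rm = TRUE)))
}
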