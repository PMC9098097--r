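#' Per-spectrum normalisation
#'
#' `peak_normalize()` rescales each spectrum to the unit interval.  The
#' default `"minmax"` mode computes `(x - min x) / (max x - min x)`, so that
#' every spectrum spans exactly \[0, 1\] — the scale on which the fingerprint
#' band amplitudes of lung tissue are tabulated.  Mode `"literal"` divides by
#' `max x` instead of the range, i.e. `(x - min x) / max x`.
#' `zscore_normalize()` centres and scales each spectrum to mean 0 and
#' (sample) standard deviation 1, the normalisation used for classifier
#' training inputs.  Both operate strictly per spectrum: no other row of the
#' dataset influences the result.
#'
#' @param data an [ftir_dataset()] or a bare numeric vector.
#' @param mode `"minmax"` (default) or `"literal"`.
#' @return Object of the same shape as `data`, normalised per spectrum.
#' @export
#' @examples
#' peak_normalize(c(0.2, 0.5, 1.0, 0.4))
#' zscore_normalize(c(1, 2, 3))
peak_normalize <- function(data, mode = c("minmax", "literal")) {
  mode <- match.arg(mode)
  per_spectrum(data, function(x, id) {
    lo <- min(x); hi <- max(x)
    if (mode == "minmax") {
      if (hi == lo) stop("constant spectrum cannot be peak-normalized: ",
                         id, call. = FALSE)
      (x - lo) / (hi - lo)
    } else {
      if (hi == 0) stop("peak normalization (literal) needs max != 0: ",
                        id, call. = FALSE)
      (x - lo) / hi
    }
  })
}

#' @rdname peak_normalize
#' @export
zscore_normalize <- function(data) {
  per_spectrum(data, function(x, id) {
    s <- stats::sd(x)
    if (s == 0) stop("zero-variance spectrum cannot be z-scored: ", id,
                     call. = FALSE)
    (x - mean(x)) / s
  })
}

per_spectrum <- function(data, f) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) < 2) stop("a spectrum needs >= 2 points", call. = FALSE)
    return(f(data, "<vector>"))
  }
  m <- spectra_matrix(data)
  for (i in seq_len(nrow(m))) m[i, ] <- f(m[i, ], data$id[i])
  replace_spectra(data, m)
}

#' Rubber-band baseline correction
#'
#' Subtracts the "rubber band" stretched beneath a spectrum: the lower convex
#' hull of the points (wavenumber, absorbance), linearly interpolated onto
#' the full grid.  The hull is seeded by splitting the ascending wavenumber
#' axis into `n_baseline_points` equal segments and taking the minimum of
#' each (plus both grid endpoints); any point still below the resulting
#' envelope is then added and the hull recomputed, so the converged envelope
#' is the lower convex hull of the whole spectrum.  The corrected spectrum is
#' therefore non-negative, touches zero at every anchor, and is exactly
#' invariant to adding a linear ramp to the input.
#'
#' @param x numeric absorbance vector (aligned to `w`), or an
#'   [ftir_dataset()] (then every spectrum is corrected and the dataset
#'   returned).
#' @param w wavenumber vector; defaults to an equispaced index grid for bare
#'   vectors and the dataset grid otherwise.
#' @param n_baseline_points number of seeding segments (>= 2); 64 is the
#'   instrument-software convention for tissue spectra.
#' @return For a vector: list with `baseline`, `corrected` and
#'   `anchor_indices` (indices into the input ordering).  For a dataset: the
#'   corrected dataset.
#' @export
rubberband_correct <- function(x, w = NULL, n_baseline_points = 64) {
  if (n_baseline_points < 2) stop("n_baseline_points must be >= 2",
                                  call. = FALSE)
  if (!is.null(dim(x)) || inherits(x, "ftir_dataset")) {
    m <- spectra_matrix(x)
    for (i in seq_len(nrow(m))) {
      m[i, ] <- rubberband_correct(m[i, ], wavenumbers(x),
                                   n_baseline_points)$corrected
    }
    return(replace_spectra(x, m))
  }
  n <- length(x)
  if (n_baseline_points > n) n_baseline_points <- n
  if (is.null(w)) w <- seq_len(n)
  # work on the ascending axis
  ord <- order(w)
  t <- w[ord]; y <- x[ord]
  seg <- pmin(floor((seq_len(n) - 1) / n * n_baseline_points) + 1,
              n_baseline_points)
  cand <- sort(unique(c(1L, n,
                        vapply(split(seq_len(n), seg),
                               function(ix) ix[which.min(y[ix])], 1L))))
  repeat {
    hull <- lower_hull(t[cand], y[cand])
    anchors <- cand[hull]
    base <- stats::approx(t[anchors], y[anchors], xout = t, rule = 2)$y
    below <- which(y < base - 1e-12)
    if (!length(below)) break
    cand <- sort(unique(c(cand, below)))
  }
  corrected <- y - base
  corrected[corrected < 0] <- 0
  back <- order(ord)
  list(baseline = base[back], corrected = corrected[back],
       anchor_indices = sort(ord[anchors]))
}

# indices (into the given points, assumed sorted by t) of the lower convex
# hull, by Andrew's monotone chain
lower_hull <- function(t, y) {
  n <- length(t)
  if (n <= 2) return(seq_len(n))
  h <- integer(0)
  for (i in seq_len(n)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      # drop b if it lies on/above segment a--i
      if ((t[b] - t[a]) * (y[i] - y[a]) - (t[i] - t[a]) * (y[b] - y[a]) <= 0) {
        h <- h[-length(h)]
      } else break
    }
    h <- c(h, i)
  }
  h
}

#' Robust screening of deviant spectra
#'
#' Flags spectra whose shape deviates strongly from their class consensus.
#' Each sample's deviation is the mean over grid points of the absolute
#' difference to its class's pointwise-median spectrum (the integrated
#' band-profile deviation); the score is that deviation divided by the
#' class median deviation (a MAD-type ratio).  Samples with score above
#' `threshold_mads` are removed.  The mean, not the median, is used across
#' grid points: absorption bands cover only part of the fingerprint grid,
#' and a median-based deviation can miss a sample whose peaks are grossly
#' aberrant but whose between-band baseline is ordinary.
#'
#' @param data an [ftir_dataset()] with >= 3 spectra per class.
#' @param threshold_mads flagging threshold on the deviation score.
#' @param exclude_ids optional explicit sample ids to remove regardless of
#'   score (an audit override).
#' @return List with `data` (survivors, original order) and `report`
#'   (tibble: id, label, score, flagged, plus the threshold as an attribute).
#' @export
remove_outliers <- function(data, threshold_mads = 3.5, exclude_ids = NULL) {
  cnt <- table(data$label[data$label != "unknown"])
  if (any(cnt < 3)) stop("need >= 3 spectra per class to screen outliers",
                         call. = FALSE)
  m <- spectra_matrix(data)
  score <- rep(NA_real_, nrow(m))
  for (cl in unique(data$label)) {
    ix <- which(data$label == cl)
    med <- apply(m[ix, , drop = FALSE], 2, stats::median)
    dev <- rowMeans(abs(sweep(m[ix, , drop = FALSE], 2, med)))
    score[ix] <- dev / stats::median(dev)
  }
  flagged <- score > threshold_mads | data$id %in% exclude_ids
  if (all(flagged)) stop("all samples flagged; threshold too aggressive",
                         call. = FALSE)
  report <- tibble::tibble(id = data$id, label = data$label,
                           score = score, flagged = flagged)
  attr(report, "threshold") <- threshold_mads
  survivors <- data[!flagged, , drop = FALSE]
  class(survivors) <- class(data)
  attr(survivors, "provenance") <- c(attr(data, "provenance"),
                                     sprintf("outlier screen removed %d of %d",
                                             sum(flagged), nrow(data)))
  list(data = survivors, report = report)
}
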