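#' FTIR spectral datasets
#'
#' An `ftir_dataset` is a wide tibble with one row per measured spectrum:
#' a character column `id`, a character column `label` (one of `"benign"`,
#' `"malignant"`, `"unknown"`) and one numeric column per wavenumber, named
#' by the wavenumber in cm^-1.  The wavenumber grid is stored high-to-low
#' (1800 down to 850 for the fingerprint region), matching the export
#' convention of FTIR instruments.
#'
#' @param absorbance numeric matrix, one row per spectrum, one column per
#'   grid point (columns aligned to `wavenumbers`).
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   decreasing, all within 400--4000.
#' @param ids character vector of unique sample identifiers.
#' @param labels character vector of class labels; missing labels are
#'   stored as `"unknown"`.
#' @param provenance free-text metadata attached as an attribute.
#'
#' @return A tibble of class `ftir_dataset`.
#' @export
#' @examples
#' grid <- default_grid()
#' x <- ftir_dataset(matrix(runif(2 * length(grid)), 2), grid,
#'                   ids = c("a", "b"), labels = c("benign", "malignant"))
#' n_spectra(x)
ftir_dataset <- function(absorbance, wavenumbers, ids = NULL, labels = NULL,
                         provenance = character()) {
  absorbance <- as.matrix(absorbance)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(absorbance)))
  if (is.null(labels)) labels <- rep("unknown", nrow(absorbance))
  labels <- as.character(labels)
  labels[is.na(labels)] <- "unknown"
  validate_grid(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(wavenumbers), " points", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("benign", "malignant", "unknown"))
  if (length(bad)) {
    stop("labels must be 'benign', 'malignant' or 'unknown'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  colnames(absorbance) <- format_wavenumber(wavenumbers)
  out <- tibble::tibble(id = as.character(ids), label = labels)
  out <- dplyr::bind_cols(out, tibble::as_tibble(absorbance))
  attr(out, "provenance") <- provenance
  class(out) <- c("ftir_dataset", class(tibble::tibble()))
  out
}

format_wavenumber <- function(w) {
  format(w, digits = 15, trim = TRUE, scientific = FALSE)
}

validate_grid <- function(w) {
  if (length(w) < 2) stop("the wavenumber grid needs >= 2 points", call. = FALSE)
  if (any(diff(w) >= 0)) {
    stop("wavenumber grid must be strictly decreasing (high -> low)",
         call. = FALSE)
  }
  if (any(w < 400 | w > 4000)) {
    stop("wavenumbers must lie within [400, 4000] cm^-1", call. = FALSE)
  }
  invisible(w)
}

#' The canonical 462-point fingerprint grid
#'
#' 462 equally spaced wavenumbers from 1800 down to 850 cm^-1 inclusive
#' (step 950/461, about 2.06 cm^-1), the grid on which the lung-tissue
#' spectra were recorded.
#'
#' @return Numeric vector of length 462, strictly decreasing.
#' @export
default_grid <- function() {
  seq(1800, 850, length.out = 462)
}

#' @rdname ftir_dataset
#' @param x an `ftir_dataset`.
#' @export
wavenumbers <- function(x) {
  as.numeric(setdiff(names(x), c("id", "label")))
}

#' @rdname ftir_dataset
#' @export
spectra_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), c("id", "label")), drop = FALSE])
  rownames(m) <- x$id
  m
}

#' @rdname ftir_dataset
#' @export
n_spectra <- function(x) nrow(x)

#' @rdname ftir_dataset
#' @export
class_counts <- function(x) table(factor(x$label,
                                         c("benign", "malignant", "unknown")))

# Rebuild an ftir_dataset from a template's ids/labels and a new matrix.
replace_spectra <- function(x, m, wavenumbers_new = NULL) {
  ftir_dataset(m,
               wavenumbers = wavenumbers_new %||% wavenumbers(x),
               ids = x$id, labels = x$label,
               provenance = attr(x, "provenance"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ftir_dataset <- function(x, ...) {
  w <- wavenumbers(x)
  cnt <- class_counts(x)
  cat(sprintf(
    "<ftir_dataset> %d spectra x %d wavenumbers (%.6g to %.6g cm^-1)\n",
    nrow(x), length(w), w[1], w[length(w)]))
  cat(sprintf("  benign: %d  malignant: %d  unknown: %d\n",
              cnt[["benign"]], cnt[["malignant"]], cnt[["unknown"]]))
  NextMethod()
}
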