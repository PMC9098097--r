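#' Read and write spectral datasets
#'
#' Spectra are exchanged as a wide CSV: column 1 `id`, remaining column
#' headers numeric wavenumbers in cm^-1 (high to low), one row per sample.
#' Labels travel in a second CSV with columns `id,label`
#' (label in `benign`/`malignant`); samples without a label entry are
#' loaded as `unknown`.
#'
#' @param spectra_path path of the wide spectra CSV.
#' @param labels_path optional path of the label CSV.
#' @return [read_spectra()] returns an [ftir_dataset()];
#'   [write_spectra()] returns its input invisibly.
#' @export
read_spectra <- function(spectra_path, labels_path = NULL) {
  header <- strsplit(readLines(spectra_path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "id") {
    stop("expected a wide CSV with header 'id,<wavenumber>,...': ",
         spectra_path, call. = FALSE)
  }
  grid <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(grid)) {
    stop("non-numeric wavenumber header column(s): ",
         paste(header[-1][is.na(grid)], collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(spectra_path, check.names = FALSE,
                         colClasses = c(id = "character"))
  if (ncol(raw) != length(grid) + 1) {
    stop("ragged rows in ", spectra_path, call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    stop("non-numeric absorbance in column '", names(raw)[-1][bad], "'",
         call. = FALSE)
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric absorbance at row %d, column '%s'",
                 idx[1], colnames(m)[idx[2]]), call. = FALSE)
  }
  # Instrument exports are high -> low; accept ascending input by reversing.
  if (length(grid) >= 2 && grid[1] < grid[length(grid)]) {
    grid <- rev(grid)
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, colClasses = "character")
    if (!all(c("id", "label") %in% names(lab))) {
      stop("label CSV must have columns id,label: ", labels_path,
           call. = FALSE)
    }
    labels <- lab$label[match(raw$id, lab$id)]
  }
  ftir_dataset(m, grid, ids = raw$id, labels = labels,
               provenance = paste("read from", spectra_path))
}

#' @rdname read_spectra
#' @param data an [ftir_dataset()].
#' @export
write_spectra <- function(data, spectra_path, labels_path = NULL) {
  w <- wavenumbers(data)
  header <- paste(c("id", format_wavenumber(w)), collapse = ",")
  m <- spectra_matrix(data)
  body <- if (nrow(m) == 0) character() else
    paste(data$id,
          apply(m, 1, function(r) {
            paste(format(r, digits = 15, trim = TRUE, scientific = TRUE),
                  collapse = ",")
          }),
          sep = ",")
  writeLines(c(header, body), spectra_path)
  if (!is.null(labels_path)) {
    keep <- data$label != "unknown"
    utils::write.csv(data.frame(id = data$id[keep], label = data$label[keep]),
                     labels_path, row.names = FALSE, quote = FALSE)
  }
  invisible(data)
}

#' Restrict a dataset to the fingerprint region
#'
#' Keeps the grid points `w` with `low <= w <= high` (closed interval, so the
#' printed endpoints 1800 and 850 cm^-1 stay in range when present).
#'
#' @param data an [ftir_dataset()].
#' @param high,low interval bounds in cm^-1.
#' @return An [ftir_dataset()] on the restricted grid.
#' @export
crop_fingerprint <- function(data, high = 1800, low = 850) {
  stopifnot(high > low)
  w <- wavenumbers(data)
  keep <- w >= low & w <= high
  if (!any(keep)) {
    stop(sprintf("no grid points inside [%g, %g] cm^-1", low, high),
         call. = FALSE)
  }
  replace_spectra(data, spectra_matrix(data)[, keep, drop = FALSE],
                  wavenumbers_new = w[keep])
}
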