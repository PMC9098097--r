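#' Principal component analysis of a spectral dataset
#'
#' Mean-centres the spectra, eigendecomposes the (unnormalised) scatter
#' matrix `t(X - colMeans) %*% (X - colMeans)` and retains the two leading
#' eigenvectors.  Scores are the projections of the centred spectra onto
#' those eigenvectors.  Eigenvector signs are fixed so that each component's
#' largest-magnitude entry is positive, making results reproducible.
#'
#' @param data an [ftir_dataset()] with >= 3 samples.
#' @return Object of class `ftir_pca`: list with `mean_spectrum`,
#'   `components` (p x 2, orthonormal columns), `eigenvalues` (all, in
#'   descending order), `explained_fraction` and `wavenumbers`.
#' @export
fit_pca <- function(data) {
  m <- spectra_matrix(data)
  if (nrow(m) < 3) stop("PCA needs at least 3 samples", call. = FALSE)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  e <- eigen(crossprod(xc), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  comp <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(comp[, j]))
    if (comp[k, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean_spectrum = mu, components = comp, eigenvalues = ev,
                 explained_fraction = ev / sum(ev),
                 wavenumbers = wavenumbers(data)),
            class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> %d variables; F1 %.2f%%, F2 %.2f%% of variance\n",
              length(x$mean_spectrum),
              100 * x$explained_fraction[1], 100 * x$explained_fraction[2]))
  invisible(x)
}

#' Project spectra onto fitted principal components
#'
#' @param data an [ftir_dataset()] on the same grid as the fitted model.
#' @param model an `ftir_pca` from [fit_pca()].
#' @return Tibble with columns `id`, `label`, `F1`, `F2`.
#' @export
project_pca <- function(data, model) {
  m <- spectra_matrix(data)
  if (ncol(m) != length(model$mean_spectrum)) {
    stop("dataset dimensionality does not match the PCA model",
         call. = FALSE)
  }
  s <- unname(sweep(m, 2, model$mean_spectrum) %*% model$components)
  tibble::tibble(id = data$id, label = data$label,
                 F1 = s[, 1], F2 = s[, 2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ftir_pca <- function(x, ...) {
  tibble::tibble(wavenumber = x$wavenumbers,
                 mean = x$mean_spectrum,
                 F1 = x$components[, 1], F2 = x$components[, 2])
}

#' @export
glance.ftir_pca <- function(x, ...) {
  tibble::tibble(explained_F1 = x$explained_fraction[1],
                 explained_F2 = x$explained_fraction[2],
                 n_components = length(x$eigenvalues))
}
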