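#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class median spectra
#'
#' @param data an [ftir_dataset()].
#' @return A ggplot: absorbance vs wavenumber (axis reversed, FTIR
#'   convention), one line per class.
#' @export
plot_median_spectra <- function(data) {
  w <- wavenumbers(data)
  classes <- setdiff(unique(data$label), "unknown")
  df <- purrr::map_dfr(classes, function(cl)
    tibble::tibble(label = cl, wavenumber = w,
                   absorbance = median_spectrum(data, cl)))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Absorbance (normalised)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ftir_pca <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    stop("supply the dataset to project: autoplot(model, data)",
         call. = FALSE)
  }
  sc <- project_pca(data, object)
  ggplot2::ggplot(sc, ggplot2::aes(.data$F1, .data$F2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("F1 (%.2f%%)", 100 * object$explained_fraction[1]),
      y = sprintf("F2 (%.2f%%)", 100 * object$explained_fraction[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ga_history <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Validation accuracy",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ftir_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$model, .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "Metric (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.pseudo_clinical <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$id, .data$median,
                                       colour = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = NULL, y = "Probability of malignancy",
                  colour = "Site diagnosis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
tidy.ftir_classifier <- function(x, ...) {
  p <- x$params
  switch(x$kind,
         lda = tibble::tibble(term = c("mu_benign", "mu_malignant", "sigma"),
                              estimate = c(p$mu_b, p$mu_m, p$sigma)),
         svm = tibble::tibble(term = c("bias", "platt_A", "platt_B",
                                       "learning_rate"),
                              estimate = c(p$b, p$A, p$B, p$learning_rate)),
         lr = tibble::tibble(term = c("bias", "learning_rate"),
                             estimate = c(p$b, p$learning_rate)),
         rf = tibble::tibble(term = "n_trees", estimate = p$n_rf),
         nb = tibble::tibble(term = sprintf("var_%d", p$vars),
                             estimate = p$thresholds),
         dt = tibble::tibble(term = "n_nodes",
                             estimate = length(p$tree)),
         nn = tibble::tibble(term = "n_parameters",
                             estimate = length(flatten_params(p$params))))
}

#' @export
glance.ftir_classifier <- function(x, ...) {
  tibble::tibble(kind = x$kind, train_accuracy = x$train_accuracy,
                 val_accuracy = x$val_accuracy)
}
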