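#' Second-opinion predictions for diagnostically discordant samples
#'
#' Retrains every supplied network design on the concordant spectra and
#' predicts each discordant sample with every (design, run) instance; the
#' per-sample probability collections are summarised by their median,
#' quartiles and mean.  With the study-scale inputs (50 tuned designs per
#' family, 10 runs each) every sample receives 500 probabilities per family.
#'
#' @param concordant,discordant [ftir_dataset()]s on the same grid
#'   (z-scoring is applied internally).
#' @param tuned_specs named list: family -> list of [nn_spec()]s (e.g. the
#'   best genomes of repeated evolution runs, via [genome_to_spec()]).
#' @param runs retrainings per design, each with a fresh seed.
#' @param confidence_level minimum median probability toward the predicted
#'   class for the `confident` flag.
#' @param max_iqr maximum interquartile range for the `confident` flag.
#' @param seed optional integer seed.
#' @return Tibble of class `pseudo_clinical` with one row per
#'   (family, sample): `n_probs`, `median`, `q25`, `q75`, `mean`,
#'   `predicted_class`, `confident`, plus the true `label`.
#' @export
run_pseudo_clinical <- function(concordant, discordant, tuned_specs,
                                runs = 10, confidence_level = 0.8,
                                max_iqr = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ztr <- zscore_normalize(concordant)
  zts <- zscore_normalize(discordant)
  xts <- spectra_matrix(zts)
  out <- list()
  for (family in names(tuned_specs)) {
    specs <- tuned_specs[[family]]
    if (!length(specs)) {
      warning("no designs supplied for family ", family, call. = FALSE)
      next
    }
    probs <- matrix(NA_real_, nrow(zts), 0)
    for (spec in specs) {
      for (r in seq_len(runs)) {
        cl <- train_network(spec, ztr)
        probs <- cbind(probs, predict_nn(cl$params, xts))
      }
    }
    out[[family]] <- tibble::tibble(
      family = family, id = zts$id, label = zts$label,
      n_probs = ncol(probs),
      median = apply(probs, 1, stats::median),
      q25 = apply(probs, 1, stats::quantile, 0.25),
      q75 = apply(probs, 1, stats::quantile, 0.75),
      mean = rowMeans(probs))
  }
  res <- dplyr::bind_rows(out)
  res$predicted_class <- ifelse(res$median > 0.5, "malignant", "benign")
  toward <- ifelse(res$median > 0.5, res$median, 1 - res$median)
  res$confident <- toward >= confidence_level &
    (res$q75 - res$q25) <= max_iqr
  class(res) <- c("pseudo_clinical", class(res))
  res
}

#' Place concordant and discordant samples on fitted principal components
#'
#' @param concordant,discordant [ftir_dataset()]s.
#' @param model an `ftir_pca` fitted on the concordant set (or compatible).
#' @return Tibble: `id`, `label`, `set` (concordant/discordant), `F1`, `F2`.
#' @export
place_on_pca <- function(concordant, discordant, model) {
  a <- project_pca(concordant, model)
  a$set <- "concordant"
  b <- project_pca(discordant, model)
  b$set <- "discordant"
  dplyr::bind_rows(a, b)[, c("id", "label", "set", "F1", "F2")]
}
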