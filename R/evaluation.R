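#' Stratified repeated train/validation/test plan
#'
#' For each of `trials` trials, draws `reps_per_trial` independent
#' stratified random splits of the dataset into training, validation and
#' test sets at the given fractions (default 70/15/15).  Per-class sizes
#' are rounded, so each set's class ratio matches the dataset's within one
#' sample.  Fully reproducible from `seed`.
#'
#' @param data an [ftir_dataset()] with both classes.
#' @param trials number of trials `T`.
#' @param reps_per_trial splits per trial `N`.
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed optional integer seed.
#' @return List of class `cv_plan`; element `[[t]][[n]]` holds integer row
#'   index vectors `train`, `val`, `test`.
#' @export
make_cv_plan <- function(data, trials = 50, reps_per_trial = 10,
                         fractions = c(0.70, 0.15, 0.15), seed = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  if (!is.null(seed)) set.seed(seed)
  classes <- split(seq_len(nrow(data)), data$label)
  for (cl in names(classes)) {
    n <- length(classes[[cl]])
    if (round(fractions[1] * n) < 1 || round(fractions[2] * n) < 1 ||
        n - round(fractions[1] * n) - round(fractions[2] * n) < 1) {
      stop("class '", cl, "' too small to stratify", call. = FALSE)
    }
  }
  plan <- lapply(seq_len(trials), function(t) {
    lapply(seq_len(reps_per_trial), function(n) {
      sets <- list(train = integer(), val = integer(), test = integer())
      for (ix in classes) {
        sh <- sample(ix)
        n_tr <- round(fractions[1] * length(ix))
        n_v <- round(fractions[2] * length(ix))
        sets$train <- c(sets$train, sh[seq_len(n_tr)])
        sets$val <- c(sets$val, sh[n_tr + seq_len(n_v)])
        sets$test <- c(sets$test, sh[-seq_len(n_tr + n_v)])
      }
      lapply(sets, sort)
    })
  })
  structure(plan, class = "cv_plan", trials = trials,
            reps_per_trial = reps_per_trial, fractions = fractions,
            n = nrow(data))
}

#' Diagnostic metrics of one prediction set
#'
#' Thresholds the probabilities at `threshold` (malignant when above) and
#' computes accuracy, positive and negative predictive values, recall
#' (sensitivity) and specificity from the confusion matrix, plus the
#' trapezoidal area under the ROC curve (ties between classes receive half
#' credit, so it equals the rank-based two-sample probability).  Ratios
#' with a zero denominator are returned as `NA`.
#'
#' @param y_true class labels (`"malignant"`/`"benign"` or 1/0).
#' @param y_prob malignancy probabilities.
#' @param threshold decision cut-off.
#' @return One-row tibble with columns `AUC`, `ACC`, `PPV`, `NPV`, `RR`,
#'   `SR` (all proportions in \[0, 1\]).
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y <- if (is.character(y_true)) label01(y_true) else as.integer(y_true)
  stopifnot(length(y) == length(y_prob))
  pred <- as.integer(y_prob > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    AUC = if (any(y == 1) && any(y == 0)) auc_trapezoid(y, y_prob)
          else NA_real_,
    ACC = safe(tp + tn, tp + tn + fp + fn),
    PPV = safe(tp, tp + fp), NPV = safe(tn, tn + fn),
    RR = safe(tp, tp + fn), SR = safe(tn, tn + fp))
}

#' @rdname compute_metrics
#' @param y 0/1 labels; `p` probabilities.
#' @param p numeric scores.
#' @export
auc_trapezoid <- function(y, p) {
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  npos <- sum(y == 1); nneg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(p >= t & y == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(p >= t & y == 0) / nneg, numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Aggregate per-fold metrics over trials
#'
#' The overall mean of a metric is the mean over trials of the per-trial
#' fold means; the overall SD is the mean over trials of the per-trial
#' fold SDs (option `pooled = TRUE` instead pools all fold values into one
#' SD).  Missing fold values are excluded.
#'
#' @param records tibble with columns `trial`, `rep` and one column per
#'   metric (as produced by [run_benchmark()], long or per-model subset).
#' @param metrics metric column names to aggregate.
#' @param pooled use the pooled SD across all fold values instead of the
#'   mean of per-trial SDs.
#' @return Tibble with columns `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(records,
                              metrics = c("AUC", "ACC", "PPV", "NPV",
                                          "RR", "SR"),
                              pooled = FALSE) {
  metrics <- intersect(metrics, names(records))
  purrr::map_dfr(metrics, function(mm) {
    v <- records[[mm]]
    per_trial <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(trial = records$trial, v = v), .data$trial),
      m = mean(.data$v, na.rm = TRUE),
      s = stats::sd(.data$v[!is.na(.data$v)]), .groups = "drop")
    tibble::tibble(metric = mm,
                   mean = mean(per_trial$m, na.rm = TRUE),
                   sd = if (pooled) stats::sd(v, na.rm = TRUE)
                        else mean(per_trial$s, na.rm = TRUE))
  })
}

#' Compare two models' metric records
#'
#' Per metric: the difference of overall means (first minus second) and a
#' two-sided Mann-Whitney p-value on the per-trial fold means.
#'
#' @param a,b metric record tibbles of the same plan dimensions.
#' @param metrics metric columns to compare.
#' @return Tibble with columns `metric`, `difference`, `p_value`,
#'   `significant`.
#' @export
compare_models <- function(a, b, metrics = c("AUC", "ACC", "PPV", "NPV",
                                             "RR", "SR")) {
  purrr::map_dfr(intersect(metrics, intersect(names(a), names(b))),
                 function(mm) {
    ta <- tapply(a[[mm]], a$trial, mean, na.rm = TRUE)
    tb <- tapply(b[[mm]], b$trial, mean, na.rm = TRUE)
    diff <- mean(ta, na.rm = TRUE) - mean(tb, na.rm = TRUE)
    p <- mann_whitney_u(ta[!is.na(ta)], tb[!is.na(tb)])$p
    tibble::tibble(metric = mm, difference = diff, p_value = p,
                   significant = p < 0.05)
  })
}

ALL_MODELS <- c("fnn2", "fnn4", "fnn8", "rnn", "cnn",
                "dt", "rf", "nb", "lda", "lr", "svm")

train_one_model <- function(kind, train, val, nn_specs, lr_grid,
                            rf_grid, rf_repeats) {
  if (kind %in% GA_FAMILIES) {
    spec <- nn_specs[[kind]]
    if (is.null(spec)) stop("no nn_spec supplied for ", kind, call. = FALSE)
    train_network(spec, train, val)
  } else {
    switch(kind,
           dt = grow_tree(train, val),
           rf = train_forest(train, val, rf_grid, rf_repeats),
           nb = train_naive_bayes(train, val),
           lda = train_lda(train),
           lr = train_logistic(train, val, lr_grid),
           svm = train_svm(train, val, lr_grid),
           stop("unknown model kind: ", kind))
  }
}

#' Benchmark all models under the repeated-split protocol
#'
#' For every (trial, repetition) split of the plan: z-score normalise each
#' spectrum, train every requested model on the training set (using the
#' validation set for its internal searches), and score the six diagnostic
#' metrics on the test set.  A model failure on one split is recorded as
#' missing and the run continues.
#'
#' @param data an [ftir_dataset()] with both classes.
#' @param plan a [make_cv_plan()] over `data`.
#' @param models character subset of
#'   `c("fnn2","fnn4","fnn8","rnn","cnn","dt","rf","nb","lda","lr","svm")`.
#' @param nn_specs named list mapping each requested network family to its
#'   [nn_spec()].
#' @param lr_grid learning-rate grid for the SVM and logistic regression.
#' @param rf_grid,rf_repeats forest tree-count search settings.
#' @param seed optional integer seed.
#' @return List of class `ftir_benchmark` with `records` (tibble: model,
#'   trial, rep, six metric columns) and `summary` (per-model aggregate,
#'   percent scale).
#' @export
run_benchmark <- function(data, plan, models = ALL_MODELS, nn_specs = NULL,
                          lr_grid = 10^seq(-4, -1), rf_grid = c(3, 10, 30),
                          rf_repeats = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zdata <- zscore_normalize(data)
  records <- list()
  for (t in seq_along(plan)) {
    for (n in seq_along(plan[[t]])) {
      sp <- plan[[t]][[n]]
      d_tr <- zdata[sp$train, ]; class(d_tr) <- class(zdata)
      d_v <- zdata[sp$val, ]; class(d_v) <- class(zdata)
      d_ts <- zdata[sp$test, ]; class(d_ts) <- class(zdata)
      for (kind in models) {
        row <- tryCatch({
          cl <- train_one_model(kind, d_tr, d_v, nn_specs, lr_grid,
                                rf_grid, rf_repeats)
          p <- predict(cl, d_ts)
          compute_metrics(d_ts$label, p)
        }, error = function(e) {
          warning("model ", kind, " failed on trial ", t, " rep ", n, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
        if (!is.null(row)) {
          records[[length(records) + 1]] <-
            dplyr::bind_cols(tibble::tibble(model = kind, trial = t,
                                            rep = n), row)
        }
      }
    }
  }
  records <- dplyr::bind_rows(records)
  summary <- purrr::map_dfr(unique(records$model), function(k) {
    agg <- aggregate_metrics(records[records$model == k, ])
    dplyr::mutate(agg, model = k, mean = 100 * .data$mean,
                  sd = 100 * .data$sd)
  })
  structure(list(records = records, summary = summary),
            class = "ftir_benchmark")
}

#' @export
print.ftir_benchmark <- function(x, ...) {
  cat("<ftir_benchmark>\n")
  wide <- tidyr::pivot_wider(x$summary,
                             names_from = "model",
                             values_from = c("mean", "sd"))
  print(wide)
  invisible(x)
}

#' @export
tidy.ftir_benchmark <- function(x, ...) x$records

#' @export
glance.ftir_benchmark <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("model", "metric", "mean")],
                     names_from = "metric", values_from = "mean")
}
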