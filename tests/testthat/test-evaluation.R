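test_that("the split plan is a stratified partition at 70/15/15", {
  d <- simulate_cohort(53, 65, seed = 71, grid = desk_grid())
  plan <- make_cv_plan(d, trials = 3, reps_per_trial = 4, seed = 72)
  frac_m <- 53 / 118
  for (t in 1:3) for (n in 1:4) {
    sp <- plan[[t]][[n]]
    all_idx <- sort(c(sp$train, sp$val, sp$test))
    expect_identical(all_idx, seq_len(118))        # disjoint union
    expect_equal(length(sp$train), 83)             # 37 + 46
    expect_equal(sum(d$label[sp$train] == "malignant"), 37)
    for (set in sp) {
      m_in <- sum(d$label[set] == "malignant")
      expect_lte(abs(m_in - frac_m * length(set)), 1)
    }
  }
  # deterministic from seed
  p2 <- make_cv_plan(d, trials = 3, reps_per_trial = 4, seed = 72)
  expect_identical(unclass(plan)[1:3], unclass(p2)[1:3])
  expect_error(make_cv_plan(subset_ds(d, c(1, 60)), 1, 1, seed = 1),
               "too small")
})

test_that("metrics match hand confusion arithmetic", {
  # TP=3 FP=1 TN=4 FN=2
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.6, 0.1, 0.2, 0.3, 0.4)
  m <- compute_metrics(y, p)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$PPV, 0.75)
  expect_equal(m$NPV, 2 / 3)
  expect_equal(m$RR, 0.6)
  expect_equal(m$SR, 0.8)
  # perfect and inverted ranking
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$AUC, 1)
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$AUC, 0)
  # hand-counted pairwise AUC
  expect_equal(compute_metrics(c(1, 0, 1, 0),
                               c(0.9, 0.8, 0.4, 0.3))$AUC, 0.75)
  # undefined ratios are missing, not errors
  m0 <- compute_metrics(c(1, 1), c(0.9, 0.8))
  expect_true(is.na(m0$NPV) && is.na(m0$SR) && is.na(m0$AUC))
})

test_that("trapezoidal AUC equals the pairwise comparison with ties", {
  pairwise <- function(y, p) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(73)
  for (k in 1:20) {
    y <- as.integer(runif(12) < 0.5)
    if (length(unique(y)) < 2) next
    p <- sample(seq(0, 1, 0.1), 12, replace = TRUE)   # plenty of ties
    expect_equal(auc_trapezoid(y, p), pairwise(y, p), tolerance = 1e-12)
  }
})

test_that("aggregation follows the trial-mean / trial-SD formulas", {
  rec <- tibble::tibble(trial = c(1, 1, 2, 2), rep = c(1, 2, 1, 2),
                        ACC = c(0.8, 1.0, 0.6, 0.6))
  agg <- aggregate_metrics(rec, metrics = "ACC")
  expect_equal(agg$mean, 0.75)
  expect_equal(agg$sd, (sd(c(0.8, 1.0)) + 0) / 2, tolerance = 1e-12)
  expect_equal(agg$sd, 0.070711, tolerance = 1e-5)
  # constant records: SD 0, mean the value
  rec2 <- tibble::tibble(trial = rep(1:3, each = 2), rep = rep(1:2, 3),
                         AUC = rep(0.9, 6))
  agg2 <- aggregate_metrics(rec2, metrics = "AUC")
  expect_equal(agg2$mean, 0.9)
  expect_equal(agg2$sd, 0)
  # brute-force double loop on random records
  set.seed(74)
  rec3 <- tibble::tibble(trial = rep(1:5, each = 4), rep = rep(1:4, 5),
                         ACC = runif(20))
  agg3 <- aggregate_metrics(rec3, metrics = "ACC")
  mt <- st <- numeric(5)
  for (t in 1:5) {
    v <- rec3$ACC[rec3$trial == t]
    mt[t] <- mean(v); st[t] <- sqrt(sum((v - mean(v))^2) / 3)
  }
  expect_equal(agg3$mean, mean(mt), tolerance = 1e-12)
  expect_equal(agg3$sd, mean(st), tolerance = 1e-12)
  # order invariance
  agg4 <- aggregate_metrics(rec3[sample(20), ], metrics = "ACC")
  expect_equal(agg3, agg4, tolerance = 1e-12)
})

test_that("model comparison is antisymmetric and null-calibrated", {
  set.seed(75)
  a <- tibble::tibble(trial = rep(1:6, each = 2), rep = rep(1:2, 6),
                      ACC = runif(12, 0.7, 1))
  b <- tibble::tibble(trial = rep(1:6, each = 2), rep = rep(1:2, 6),
                      ACC = runif(12, 0.5, 0.8))
  ab <- compare_models(a, b, "ACC")
  ba <- compare_models(b, a, "ACC")
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$p_value, ba$p_value)
  self <- compare_models(a, a, "ACC")
  expect_equal(self$difference, 0)
  expect_equal(self$p_value, 1)
})

test_that("the benchmark report covers all requested models", {
  d <- desk_cohort(14, 16, seed = 76)
  plan <- make_cv_plan(d, trials = 1, reps_per_trial = 2, seed = 77)
  bench <- run_benchmark(d, plan,
                         models = c("fnn2", "lda", "svm", "dt"),
                         nn_specs = desk_nn_specs(epochs = 10),
                         rf_grid = c(3), rf_repeats = 1, seed = 78)
  expect_setequal(unique(bench$records$model),
                  c("fnn2", "lda", "svm", "dt"))
  expect_equal(nrow(bench$records), 4 * 2)
  expect_true(all(c("AUC", "ACC", "PPV", "NPV", "RR", "SR") %in%
                    names(bench$records)))
  expect_true(all(bench$summary$mean >= 0 & bench$summary$mean <= 100))
  # well-separated classes: every model ranks near ceiling; the classical
  # models are also accurate at the 0.5 threshold (the severely dropped-out
  # network ranks well before its probabilities calibrate)
  expect_true(all(bench$records$AUC > 0.8, na.rm = TRUE))
  classical <- bench$records$model %in% c("lda", "svm", "dt")
  expect_true(all(bench$records$ACC[classical] > 0.7, na.rm = TRUE))
})
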