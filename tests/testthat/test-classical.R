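test_that("gini splits match hand results and flag degenerate nodes", {
  s <- gini_best_split(c(1, 2, 3, 4),
                       c("benign", "benign", "malignant", "malignant"))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gini, 0)
  expect_false(s$degenerate)
  d <- gini_best_split(c(1, 2, 3), rep("benign", 3))
  expect_true(d$degenerate)
  expect_equal(d$gini, 0)
})

test_that("gini splits match an exhaustive brute-force scan", {
  brute <- function(v, y) {
    cuts <- sort(unique(v))
    best <- list(gini = Inf, threshold = NA)
    for (i in seq_len(length(cuts) - 1)) {
      thr <- (cuts[i] + cuts[i + 1]) / 2
      l <- y[v <= thr]; r <- y[v > thr]
      g <- function(z) { p <- mean(z); 1 - p^2 - (1 - p)^2 }
      wg <- (length(l) * g(l) + length(r) * g(r)) / length(y)
      if (wg < best$gini - 1e-12) best <- list(gini = wg, threshold = thr)
    }
    best
  }
  set.seed(41)
  for (k in 1:10) {
    v <- round(rnorm(12), 1)
    y <- as.integer(runif(12) < 0.5)
    if (length(unique(y)) < 2 || length(unique(v)) < 2) next
    got <- gini_best_split(v, ifelse(y == 1, "malignant", "benign"))
    want <- brute(v, y)
    expect_equal(got$gini, want$gini, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("LDA reproduces the closed-form probability of malignancy", {
  # projected value midway between class means -> probability one half;
  # one SD past the benign mean -> softmax of the two density values
  pm <- list(w = 1, mu_b = 0, mu_m = 1, sigma = 1)
  expect_equal(ftirlung:::predict_lda(pm, matrix(0.5)), 0.5)
  p1 <- ftirlung:::predict_lda(pm, matrix(1))
  expect_equal(p1, 1 / (1 + exp(dnorm(1, 0, 1) - dnorm(1, 1, 1))),
               tolerance = 1e-12)
  expect_equal(p1, 0.5392, tolerance = 1e-4)
  # separable blobs train to perfect accuracy
  d <- blob_dataset(8, p = 5, sep = 5, seed = 42)
  cl <- train_lda(d)
  expect_equal(cl$train_accuracy, 1)
})

test_that("the SVM learns separable data and honours the grid contract", {
  d <- blob_dataset(8, p = 4, sep = 6, seed = 43)
  set.seed(1)
  cl <- train_svm(d, d, lr_grid = c(0.01, 0.1), epochs = 30)
  expect_equal(cl$train_accuracy, 1)
  # hinge loss at the solution is ~0
  x <- spectra_matrix(d); y <- 2 * ftirlung:::label01(d$label) - 1
  f <- drop(x %*% cl$params$w) + cl$params$b
  expect_lt(mean(pmax(0, 1 - y * f)), 0.1)
  # chosen rate attains the max validation accuracy over the grid
  set.seed(7)
  accs <- vapply(c(1e-4, 1e-2), function(lr) {
    set.seed(7)
    train_svm(d, d, lr_grid = lr, epochs = 10)$val_accuracy
  }, numeric(1))
  set.seed(7)
  both <- train_svm(d, d, lr_grid = c(1e-4, 1e-2), epochs = 10)
  expect_equal(both$val_accuracy, max(accs))
})

test_that("Platt calibration is monotone and symmetric", {
  set.seed(44)
  f <- rnorm(40, 0, 2)
  y <- as.integer(runif(40) < plogis(1.5 * f))
  pl <- ftirlung:::platt_fit(f, y)
  grid <- seq(-3, 3, 0.5)
  p <- 1 / (1 + exp(pl$A * grid + pl$B))
  expect_true(all(diff(p) > 0))           # increasing with decision value
  # balanced symmetric data: p(0) ~ 0.5
  f2 <- c(-2, -1, -0.5, 0.5, 1, 2)
  y2 <- c(0, 0, 0, 1, 1, 1)
  pl2 <- ftirlung:::platt_fit(f2, y2)
  expect_equal(1 / (1 + exp(pl2$B)), 0.5, tolerance = 1e-6)
})

test_that("logistic regression descends and starts at one half", {
  d <- blob_dataset(8, p = 4, sep = 6, seed = 45)
  set.seed(2)
  cl <- train_logistic(d, d, lr_grid = c(0.05, 0.2), epochs = 30)
  expect_equal(cl$train_accuracy, 1)
  # zero weights -> probability one half for any input
  expect_equal(ftirlung:::plogis_lin(matrix(rnorm(8), 2), numeric(4), 0),
               c(0.5, 0.5))
  # mean BCE decreases over training on average
  x <- spectra_matrix(d); y <- ftirlung:::label01(d$label)
  bce <- function(fit) mean(bce_loss(ftirlung:::plogis_lin(x, fit$w, fit$b),
                                     y))
  set.seed(3); early <- ftirlung:::sgd_logistic(x, y, 0.05, 2)
  set.seed(3); late <- ftirlung:::sgd_logistic(x, y, 0.05, 25)
  expect_lt(bce(late), bce(early))
})

test_that("the decision tree stops on validation accuracy and purity", {
  # one perfectly separating variable -> depth-1 tree, perfect accuracy
  m <- cbind(c(1, 2, 3, 10, 11, 12), rnorm(6))
  d <- toy_dataset(m, labels = rep(c("benign", "malignant"), each = 3),
                   grid = tiny_grid(2))
  cl <- grow_tree(d, d)
  expect_equal(cl$train_accuracy, 1)
  expect_equal(length(cl$params$tree), 3)  # root + 2 leaves
  # pure node: no split of a single-class dataset
  d2 <- toy_dataset(m, labels = rep("benign", 6), grid = tiny_grid(2))
  # (grow_tree needs both classes for metrics; check fit_cart directly)
  tr <- ftirlung:::fit_cart(m, rep(0L, 6), m, rep(0L, 6))
  expect_equal(length(tr), 1)
  # final tree validation accuracy never drops below the root stump
  d3 <- blob_dataset(10, p = 3, sep = 2, seed = 46, noise = 1.5)
  cl3 <- grow_tree(d3, d3)
  stump_acc <- max(mean(d3$label == "benign"), mean(d3$label == "malignant"))
  expect_gte(cl3$val_accuracy, stump_acc)
})

test_that("the forest votes in tree-count fractions and breaks ties low", {
  d <- blob_dataset(6, p = 3, sep = 6, seed = 47)
  set.seed(4)
  cl <- train_forest(d, d, tree_grid = c(3, 5), repeats = 1)
  expect_equal(cl$params$n_rf, 3)          # both perfect -> smallest wins
  p <- predict(cl, d)
  expect_true(all(abs(p * cl$params$n_rf - round(p * cl$params$n_rf)) <
                    1e-9))
  expect_equal(cl$val_accuracy, 1)
})

test_that("naive Bayes posteriors are normalised and smoothed", {
  set.seed(48)
  d <- blob_dataset(8, p = 5, sep = 5, seed = 48)
  cl <- train_naive_bayes(d, d)
  expect_equal(cl$train_accuracy, 1)
  p <- predict(cl, d)
  expect_true(all(p > 0 & p < 1))
  # smoothing bound per variable: theta in [1/(n+2), (n+1)/(n+2)]
  n1 <- sum(d$label == "malignant")
  expect_true(all(cl$params$theta1 >= 1 / (n1 + 2) - 1e-12))
  expect_true(all(cl$params$theta1 <= (n1 + 1) / (n1 + 2) + 1e-12))
  # complement posterior: P(malignant) + P(benign) = 1 by construction of
  # the two-class softmax; verify via the log-likelihood route
  pm <- cl$params
  x <- spectra_matrix(d)
  b <- sweep(x[, pm$vars, drop = FALSE], 2, pm$thresholds, ">")
  ll1 <- log(pm$prior1) + drop(b %*% log(pm$theta1) +
                                 (!b) %*% log(1 - pm$theta1))
  ll0 <- log(1 - pm$prior1) + drop(b %*% log(pm$theta0) +
                                     (!b) %*% log(1 - pm$theta0))
  post1 <- exp(ll1) / (exp(ll1) + exp(ll0))
  expect_equal(unname(post1), unname(p), tolerance = 1e-12)
})

test_that("symmetric models flip probabilities when labels flip", {
  d <- blob_dataset(8, p = 4, sep = 3, seed = 49)
  flipped <- d
  flipped$label <- ifelse(d$label == "malignant", "benign", "malignant")
  class(flipped) <- class(d)
  p_lda <- predict(train_lda(d), d)
  p_lda_f <- predict(train_lda(flipped), d)
  expect_equal(unname(p_lda_f), unname(1 - p_lda), tolerance = 1e-6)
  set.seed(5); p_lr <- predict(train_logistic(d, d, 0.05, epochs = 20), d)
  set.seed(5)
  p_lr_f <- predict(train_logistic(flipped, flipped, 0.05, epochs = 20), d)
  expect_equal(unname(p_lr_f), unname(1 - p_lr), tolerance = 1e-6)
  set.seed(6); p_svm <- predict(train_svm(d, d, 0.05, epochs = 20), d)
  set.seed(6)
  p_svm_f <- predict(train_svm(flipped, flipped, 0.05, epochs = 20), d)
  expect_equal(unname(p_svm_f), unname(1 - p_svm), tolerance = 1e-4)
})
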