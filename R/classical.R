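## Six classical classifiers, each implemented from first principles and
## sharing one contract: predict() returns the probability of malignancy.

new_classifier <- function(kind, params, train_accuracy = NA_real_,
                           val_accuracy = NA_real_) {
  structure(list(kind = kind, params = params,
                 train_accuracy = train_accuracy,
                 val_accuracy = val_accuracy),
            class = "ftir_classifier")
}

#' @export
print.ftir_classifier <- function(x, ...) {
  cat(sprintf("<ftir_classifier: %s>  train acc %.3f  val acc %.3f\n",
              x$kind, x$train_accuracy, x$val_accuracy))
  invisible(x)
}

#' Predict the probability of malignancy
#'
#' Every trained model in the package answers the same question: the
#' probability, in \[0, 1\], that a spectrum comes from malignant tissue.
#' The predicted label is `"malignant"` when that probability exceeds 0.5.
#'
#' @param object an `ftir_classifier`.
#' @param newdata an [ftir_dataset()] (or bare numeric matrix) on the same
#'   grid and normalisation the model was trained on.
#' @param type `"prob"` for probabilities, `"class"` for labels.
#' @param ... unused.
#' @return Named numeric vector of probabilities, or character labels.
#' @export
predict.ftir_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else spectra_matrix(newdata)
  p <- switch(object$kind,
              lda = predict_lda(object$params, x),
              svm = predict_svm(object$params, x),
              lr = predict_lr(object$params, x),
              dt = predict_tree_prob(object$params$tree, x),
              rf = predict_forest(object$params, x),
              nb = predict_nb(object$params, x),
              nn = predict_nn(object$params, x),
              stop("unknown classifier kind: ", object$kind))
  names(p) <- rownames(x)
  if (type == "class") ifelse(p > 0.5, "malignant", "benign") else p
}

label01 <- function(labels) as.integer(labels == "malignant")

accuracy_at_half <- function(p, y) mean((p > 0.5) == (y == 1))

## ---- linear discriminant analysis -------------------------------------

#' Fisher linear discriminant with Gaussian class densities
#'
#' Finds the discriminant direction maximising Fisher's criterion (for two
#' classes, `w` solves `S_W w = mu_M - mu_B`, with a small ridge
#' `1e-6 * tr(S_W)/p` on the within-class scatter since 462 variables far
#' exceed the sample count).  The probability of malignancy is the softmax
#' of the two Gaussian density values at the projected point, both with
#' SD equal to the distance between the projected class means.
#'
#' @param train an [ftir_dataset()] with both classes, z-score normalised.
#' @param ridge relative ridge added to the within-class scatter diagonal.
#' @return An `ftir_classifier`.
#' @export
train_lda <- function(train, ridge = 1e-6) {
  x <- spectra_matrix(train)
  y <- label01(train$label)
  stopifnot(any(y == 1), any(y == 0))
  mu_b <- colMeans(x[y == 0, , drop = FALSE])
  mu_m <- colMeans(x[y == 1, , drop = FALSE])
  sw <- crossprod(sweep(x[y == 0, , drop = FALSE], 2, mu_b)) +
    crossprod(sweep(x[y == 1, , drop = FALSE], 2, mu_m))
  diag(sw) <- diag(sw) + ridge * sum(diag(sw)) / ncol(x)
  w <- solve(sw, mu_m - mu_b)
  w <- w / sqrt(sum(w^2))
  s <- drop(x %*% w)
  pm <- list(w = w, mu_b = mean(s[y == 0]), mu_m = mean(s[y == 1]))
  pm$sigma <- abs(pm$mu_m - pm$mu_b)
  if (pm$sigma == 0) stop("classes indistinguishable on the discriminant",
                          call. = FALSE)
  cl <- new_classifier("lda", pm)
  cl$train_accuracy <- accuracy_at_half(predict_lda(pm, x), y)
  cl
}

predict_lda <- function(pm, x) {
  s <- drop(x %*% pm$w)
  db <- stats::dnorm(s, pm$mu_b, pm$sigma)
  dm <- stats::dnorm(s, pm$mu_m, pm$sigma)
  1 / (1 + exp(db - dm))      # softmax of the two density values
}

## ---- linear SVM with Platt calibration --------------------------------

#' Linear soft-margin SVM trained by SGD, with Platt probabilities
#'
#' Minimises `lambda * ||w||^2 / 2 + mean hinge loss` by per-sample
#' stochastic gradient descent.  The SGD learning rate is chosen by grid
#' search on validation accuracy (ties favour the smaller rate), and a Platt
#' sigmoid `1 / (1 + exp(A f + B))` is then fitted by Newton iteration to
#' the training decision values with the regularised targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`.
#'
#' @param train,val [ftir_dataset()]s with both classes, z-scored.
#' @param lr_grid candidate SGD learning rates.
#' @param lambda ridge constant of the margin term.
#' @param epochs SGD epochs.
#' @return An `ftir_classifier`.
#' @export
train_svm <- function(train, val, lr_grid = 10^seq(-4, -1),
                      lambda = 1e-3, epochs = 50) {
  if (!length(lr_grid)) stop("lr_grid must be non-empty", call. = FALSE)
  x <- spectra_matrix(train); y <- label01(train$label)
  xv <- spectra_matrix(val); yv <- label01(val$label)
  ys <- 2 * y - 1
  fits <- lapply(sort(lr_grid), function(lr) {
    fit <- sgd_hinge(x, ys, lr, lambda, epochs)
    acc <- accuracy_at_half(
      as.numeric(drop(xv %*% fit$w) + fit$b > 0), yv)
    list(lr = lr, fit = fit, val_acc = acc)
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "val_acc"))]]
  f_tr <- drop(x %*% best$fit$w) + best$fit$b
  platt <- platt_fit(f_tr, y)
  pm <- list(w = best$fit$w, b = best$fit$b, A = platt$A, B = platt$B,
             learning_rate = best$lr)
  cl <- new_classifier("svm", pm,
                       train_accuracy = accuracy_at_half(predict_svm(pm, x), y),
                       val_accuracy = best$val_acc)
  cl
}

sgd_hinge <- function(x, ys, lr, lambda, epochs) {
  w <- numeric(ncol(x)); b <- 0
  n <- nrow(x)
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      f <- sum(w * x[i, ]) + b
      if (ys[i] * f < 1) {
        w <- w - lr * (lambda * w - ys[i] * x[i, ])
        b <- b + lr * ys[i]
      } else {
        w <- w - lr * lambda * w
      }
    }
  }
  list(w = w, b = b)
}

predict_svm <- function(pm, x) {
  f <- drop(x %*% pm$w) + pm$b
  1 / (1 + exp(pm$A * f + pm$B))
}

# Platt's sigmoid fit (Newton with backtracking, regularised targets)
platt_fit <- function(f, y, max_iter = 100) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  a <- 0; b <- log((n0 + 1) / (n1 + 1))
  obj <- function(a, b) {
    z <- a * f + b
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(a, b)
  for (it in seq_len(max_iter)) {
    z <- a * f + b
    p <- 1 / (1 + exp(z))
    d1 <- t - p                     # dobj/dz
    d2 <- p * (1 - p)
    g <- c(sum(d1 * f), sum(d1))
    h <- matrix(c(sum(d2 * f * f) + 1e-12, sum(d2 * f),
                  sum(d2 * f), sum(d2) + 1e-12), 2)
    step <- solve(h, g)
    s <- 1
    repeat {
      a2 <- a - s * step[1]; b2 <- b - s * step[2]
      v2 <- obj(a2, b2)
      if (v2 < val + 1e-12 || s < 1e-10) break
      s <- s / 2
    }
    conv <- abs(val - v2) < 1e-12
    a <- a2; b <- b2; val <- v2
    if (conv || max(abs(g)) < 1e-10) break
  }
  list(A = a, B = b)
}

## ---- logistic regression ----------------------------------------------

#' Logistic regression trained by SGD on binary cross-entropy
#'
#' A linear classifier with sigmoid output, trained per-sample by SGD; the
#' learning rate is grid-searched on validation accuracy exactly as for the
#' SVM.  Weights start at zero, so the untrained model outputs 0.5.
#'
#' @inheritParams train_svm
#' @return An `ftir_classifier`.
#' @export
train_logistic <- function(train, val, lr_grid = 10^seq(-4, -1),
                           epochs = 50) {
  if (!length(lr_grid)) stop("lr_grid must be non-empty", call. = FALSE)
  x <- spectra_matrix(train); y <- label01(train$label)
  xv <- spectra_matrix(val); yv <- label01(val$label)
  fits <- lapply(sort(lr_grid), function(lr) {
    fit <- sgd_logistic(x, y, lr, epochs)
    acc <- accuracy_at_half(plogis_lin(xv, fit$w, fit$b), yv)
    list(lr = lr, fit = fit, val_acc = acc)
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "val_acc"))]]
  pm <- list(w = best$fit$w, b = best$fit$b, learning_rate = best$lr)
  new_classifier("lr", pm,
                 train_accuracy = accuracy_at_half(plogis_lin(x, pm$w, pm$b), y),
                 val_accuracy = best$val_acc)
}

sgd_logistic <- function(x, y, lr, epochs) {
  w <- numeric(ncol(x)); b <- 0
  n <- nrow(x)
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      p <- 1 / (1 + exp(-(sum(w * x[i, ]) + b)))
      g <- p - y[i]
      w <- w - lr * g * x[i, ]
      b <- b - lr * g
    }
  }
  list(w = w, b = b)
}

plogis_lin <- function(x, w, b) 1 / (1 + exp(-(drop(x %*% w) + b)))

predict_lr <- function(pm, x) plogis_lin(x, pm$w, pm$b)

## ---- decision tree ----------------------------------------------------

#' Gini-optimal split of one continuous variable
#'
#' Scans every midpoint between adjacent distinct sorted values and returns
#' the threshold minimising the weighted Gini impurity of the two induced
#' partitions; ties are broken toward the lowest threshold.
#'
#' @param values numeric vector of one variable.
#' @param labels class labels (`"benign"`/`"malignant"`) of the same length.
#' @return List with `threshold`, `gini` and `degenerate` (TRUE when only
#'   one class is present, in which case the impurity is 0 and no threshold
#'   is proposed).
#' @export
#' @examples
#' gini_best_split(c(1, 2, 3, 4), c("benign", "benign",
#'                                  "malignant", "malignant"))
gini_best_split <- function(values, labels) {
  y <- label01(labels)
  n <- length(y)
  stopifnot(n >= 2, length(values) == n)
  if (all(y == y[1])) {
    return(list(threshold = NA_real_, gini = 0, degenerate = TRUE))
  }
  ord <- order(values)
  v <- values[ord]; ys <- y[ord]
  cuts <- which(diff(v) > 0)              # split after position i
  if (!length(cuts)) {
    return(list(threshold = NA_real_, gini = 0.5, degenerate = TRUE))
  }
  c1 <- cumsum(ys)
  nl <- cuts
  n1l <- c1[cuts]
  n1r <- sum(ys) - n1l
  nr <- n - nl
  gl <- 1 - (n1l / nl)^2 - (1 - n1l / nl)^2
  gr <- 1 - (n1r / nr)^2 - (1 - n1r / nr)^2
  wg <- (nl * gl + nr * gr) / n
  k <- which(wg <= min(wg) + 1e-12)[1]    # lowest threshold on ties
  list(threshold = (v[cuts[k]] + v[cuts[k] + 1]) / 2, gini = wg[k],
       degenerate = FALSE)
}

# best (variable, threshold) over all columns; ties -> lowest column index
best_split_matrix <- function(x, y) {
  best <- NULL
  for (j in seq_len(ncol(x))) {
    s <- gini_best_split(x[, j], ifelse(y == 1, "malignant", "benign"))
    if (s$degenerate) next
    if (is.null(best) || s$gini < best$gini - 1e-12) {
      best <- list(var = j, threshold = s$threshold, gini = s$gini)
    }
  }
  best
}

#' CART decision tree with validation-guided stopping
#'
#' Grows a binary tree: at each node the Gini-optimal (variable, threshold)
#' split over all variables is proposed and accepted only if the whole
#' tree's validation accuracy does not decrease; otherwise the node stays a
#' leaf.  Leaf probability is the malignant fraction of its training
#' samples, so an exactly tied leaf predicts benign.
#'
#' @param train,val [ftir_dataset()]s with both classes.
#' @return An `ftir_classifier` whose parameters hold the node table.
#' @export
grow_tree <- function(train, val) {
  x <- spectra_matrix(train); y <- label01(train$label)
  xv <- spectra_matrix(val); yv <- label01(val$label)
  tree <- fit_cart(x, y, xv, yv)
  cl <- new_classifier("dt", list(tree = tree))
  cl$train_accuracy <- accuracy_at_half(predict_tree_prob(tree, x), y)
  cl$val_accuracy <- accuracy_at_half(predict_tree_prob(tree, xv), yv)
  cl
}

# tree as a growing data.frame of nodes; environment-based recursion
fit_cart <- function(x, y, xv, yv) {
  env <- new.env()
  env$nodes <- list(list(leaf = TRUE, prob = mean(y), var = NA, thr = NA,
                         left = NA, right = NA))
  cur_acc <- function() accuracy_at_half(predict_tree_prob(env$nodes, xv), yv)
  env$acc <- cur_acc()
  split_node <- function(id, idx) {
    yy <- y[idx]
    if (length(idx) < 2 || all(yy == yy[1])) return(invisible())
    s <- best_split_matrix(x[idx, , drop = FALSE], yy)
    if (is.null(s)) return(invisible())
    go <- x[idx, s$var] <= s$threshold
    if (!any(go) || all(go)) return(invisible())
    saved <- env$nodes
    lid <- length(env$nodes) + 1L; rid <- lid + 1L
    env$nodes[[id]] <- list(leaf = FALSE, prob = mean(yy), var = s$var,
                            thr = s$threshold, left = lid, right = rid)
    env$nodes[[lid]] <- list(leaf = TRUE, prob = mean(yy[go]), var = NA,
                             thr = NA, left = NA, right = NA)
    env$nodes[[rid]] <- list(leaf = TRUE, prob = mean(yy[!go]), var = NA,
                             thr = NA, left = NA, right = NA)
    new_acc <- cur_acc()
    if (new_acc < env$acc) {
      env$nodes <- saved                 # reject: validation got worse
      return(invisible())
    }
    env$acc <- new_acc
    split_node(lid, idx[go])
    split_node(rid, idx[!go])
  }
  split_node(1L, seq_along(y))
  env$nodes
}

predict_tree_prob <- function(nodes, x) {
  apply(x, 1, function(r) {
    id <- 1L
    while (!nodes[[id]]$leaf) {
      id <- if (r[nodes[[id]]$var] <= nodes[[id]]$thr) nodes[[id]]$left
            else nodes[[id]]$right
    }
    nodes[[id]]$prob
  })
}

## ---- random forest -----------------------------------------------------

#' Bagged CART forest with grid-searched tree count
#'
#' Grows trees on bootstrap resamples of the training set (each tree uses
#' the same validation-guided stopping as [grow_tree()]); the forest's
#' probability is the fraction of trees voting malignant.  The tree count is
#' chosen from `tree_grid` by mean validation accuracy over `repeats`
#' refits, ties going to the smallest count.
#'
#' @param train,val [ftir_dataset()]s with both classes.
#' @param tree_grid candidate numbers of trees.
#' @param repeats refits per grid value when scoring it.
#' @return An `ftir_classifier`.
#' @export
train_forest <- function(train, val, tree_grid = c(3, 10, 30), repeats = 3) {
  x <- spectra_matrix(train); y <- label01(train$label)
  xv <- spectra_matrix(val); yv <- label01(val$label)
  grid <- sort(tree_grid)
  score <- vapply(grid, function(nt) {
    mean(vapply(seq_len(repeats), function(r) {
      f <- fit_forest(x, y, xv, yv, nt)
      accuracy_at_half(predict_forest(list(trees = f), xv), yv)
    }, numeric(1)))
  }, numeric(1))
  n_rf <- grid[which.max(score)]          # which.max: first max = smallest
  trees <- fit_forest(x, y, xv, yv, n_rf)
  pm <- list(trees = trees, n_rf = n_rf)
  new_classifier("rf", pm,
                 train_accuracy = accuracy_at_half(predict_forest(pm, x), y),
                 val_accuracy = accuracy_at_half(predict_forest(pm, xv), yv))
}

fit_forest <- function(x, y, xv, yv, n_trees) {
  lapply(seq_len(n_trees), function(b) {
    repeat {
      ix <- sample.int(nrow(x), replace = TRUE)
      if (length(unique(y[ix])) == 2) break
    }
    fit_cart(x[ix, , drop = FALSE], y[ix], xv, yv)
  })
}

predict_forest <- function(pm, x) {
  votes <- vapply(pm$trees, function(tr) predict_tree_prob(tr, x) > 0.5,
                  logical(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

## ---- naive Bayes -------------------------------------------------------

#' Bernoulli naive Bayes on Gini-binarised variables
#'
#' Each variable is binarised at its own Gini-optimal threshold; variables
#' are ranked by ascending Gini impurity and added to a Bernoulli naive
#' Bayes model (add-one smoothing) three at a time upward from k = 3,
#' stopping when validation accuracy decreases; the best k is kept.
#'
#' @param train,val [ftir_dataset()]s with both classes.
#' @param k_min starting number of variables.
#' @param trials evaluations averaged per k (the fit itself is
#'   deterministic, so repeats only matter if the caller resamples).
#' @return An `ftir_classifier`.
#' @export
train_naive_bayes <- function(train, val, k_min = 3, trials = 1) {
  x <- spectra_matrix(train); y <- label01(train$label)
  xv <- spectra_matrix(val); yv <- label01(val$label)
  p <- ncol(x)
  splits <- lapply(seq_len(p), function(j)
    gini_best_split(x[, j], train$label))
  gini <- vapply(splits, `[[`, 0, "gini")
  thr <- vapply(splits, `[[`, 0, "threshold")
  usable <- which(!is.na(thr))
  rank <- usable[order(gini[usable])]
  best <- NULL; prev_acc <- -Inf
  for (k in seq(k_min, length(rank))) {
    vars <- rank[seq_len(k)]
    fit <- nb_fit(x[, vars, drop = FALSE] , y, thr[vars])
    fit$vars <- vars
    acc <- mean(vapply(seq_len(trials), function(tr)
      accuracy_at_half(predict_nb(fit, xv), yv), numeric(1)))
    if (is.null(best) || acc > best$acc) best <- list(fit = fit, acc = acc,
                                                      k = k)
    if (acc < prev_acc) break
    prev_acc <- acc
  }
  pm <- best$fit
  new_classifier("nb", pm,
                 train_accuracy = accuracy_at_half(predict_nb(pm, x), y),
                 val_accuracy = best$acc)
}

nb_fit <- function(x, y, thresholds) {
  b <- sweep(x, 2, thresholds, ">")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  theta1 <- (colSums(b[y == 1, , drop = FALSE]) + 1) / (n1 + 2)
  theta0 <- (colSums(b[y == 0, , drop = FALSE]) + 1) / (n0 + 2)
  list(thresholds = thresholds, theta1 = theta1, theta0 = theta0,
       prior1 = n1 / (n1 + n0))
}

predict_nb <- function(pm, x) {
  b <- sweep(x[, pm$vars %||% seq_along(pm$thresholds), drop = FALSE],
             2, pm$thresholds, ">")
  ll1 <- log(pm$prior1) +
    drop(b %*% log(pm$theta1) + (!b) %*% log(1 - pm$theta1))
  ll0 <- log(1 - pm$prior1) +
    drop(b %*% log(pm$theta0) + (!b) %*% log(1 - pm$theta0))
  1 / (1 + exp(ll0 - ll1))
}
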