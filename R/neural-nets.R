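## Self-normalising neural networks: a shared SELU/alpha-dropout/AdaGrad
## training core and three architectures (feed-forward, partitioned-input
## recurrent, 1-D convolutional), all with analytic backpropagation.

SELU_LAMBDA <- 1.0507009873554804934193349852946
SELU_ALPHA <- 1.6732632423543772848170429916717

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for positive `x` and
#' `lambda * alpha * (exp(x) - 1)` otherwise, with the standard
#' self-normalising constants `lambda ~ 1.05070099`, `alpha ~ 1.67326324`.
#'
#' @param x numeric.
#' @return `selu()`: the activation; `selu_grad()`: its derivative.
#' @export
#' @examples
#' selu(0); selu(1)
selu <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
}

#' @rdname selu
#' @export
selu_grad <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
}

#' Binary cross-entropy of a malignancy probability
#'
#' `-(y log p + (1 - y) log(1 - p))` with `y = 1` for malignant; the
#' probability is clipped to `[1e-12, 1 - 1e-12]` first.  Applied to the
#' malignant component of the two-unit softmax head this equals the
#' two-class cross-entropy.
#'
#' @param prob_malignant probability in \[0, 1\].
#' @param label `"malignant"`/`"benign"` or 1/0.
#' @return Non-negative loss value.
#' @export
bce_loss <- function(prob_malignant, label) {
  y <- if (is.character(label)) as.integer(label == "malignant")
       else as.integer(label)
  p <- pmin(pmax(prob_malignant, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Split a spectrum into contiguous chunks for the recurrent network
#'
#' The input is cut into `partitions` contiguous chunks of size
#' `ceiling(length(x) / partitions)`; the last chunk is zero-padded to equal
#' length.  Returned as a matrix with one column per time step.
#'
#' @param x numeric vector.
#' @param partitions number of chunks (>= 1, <= length(x)).
#' @return Numeric matrix `chunk_size x partitions`.
#' @export
partition_input <- function(x, partitions) {
  if (partitions < 1 || partitions > length(x)) {
    stop("partitions must be between 1 and length(x)", call. = FALSE)
  }
  m <- ceiling(length(x) / partitions)
  matrix(c(x, numeric(m * partitions - length(x))), nrow = m)
}

#' Neural-network hyperparameter specification
#'
#' Bundles the tunable hyperparameters of one network.  Families:
#' `"fnn"` — `depth` dense SELU layers of `neurons` units; `"rnn"` — the
#' input split into `partitions` chunks fed through a single gate-free SELU
#' recurrent layer of `neurons_per_fold` units, whose final state passes
#' through one dense SELU layer of `neurons` units; `"cnn"` —
#' `conv_layers` valid (no padding) 1-D convolutions of `filter_size` taps
#' and stride `filter_skip`, with `base_kernels * 2^(layer-1)` kernels in
#' each layer, flattened into one dense SELU layer of `neurons` units.
#' Every hidden layer output feeds a two-unit softmax head; alpha-dropout at
#' `dropout_rate` is applied to dense hidden layers during training only.
#'
#' @param family `"fnn"`, `"rnn"` or `"cnn"`.
#' @param epochs training epochs (per-sample SGD).
#' @param learning_rate AdaGrad learning rate.
#' @param adagrad_epsilon AdaGrad stabilising constant.
#' @param neurons dense-layer width.
#' @param depth number of dense layers (FNN).
#' @param partitions number of input chunks (RNN).
#' @param neurons_per_fold recurrent state width (RNN).
#' @param conv_layers,filter_size,filter_skip,base_kernels CNN geometry;
#'   `filter_skip` must not exceed `filter_size`.
#' @param dropout_rate alpha-dropout drop probability in \[0, 1).
#' @return A list of class `nn_spec`.
#' @export
nn_spec <- function(family = c("fnn", "rnn", "cnn"), epochs = 50,
                    learning_rate = 1e-2, adagrad_epsilon = 1e-6,
                    neurons = 17, depth = 2, partitions = 10,
                    neurons_per_fold = 24, conv_layers = 2, filter_size = 8,
                    filter_skip = 4, base_kernels = 8, dropout_rate = 0.9) {
  family <- match.arg(family)
  stopifnot(epochs >= 0, learning_rate > 0, adagrad_epsilon > 0,
            neurons >= 1, dropout_rate >= 0, dropout_rate < 1)
  if (family == "cnn" && filter_skip > filter_size) {
    stop("filter_skip must not exceed filter_size", call. = FALSE)
  }
  structure(list(family = family, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 adagrad_epsilon = adagrad_epsilon, neurons = as.integer(neurons),
                 depth = as.integer(depth), partitions = as.integer(partitions),
                 neurons_per_fold = as.integer(neurons_per_fold),
                 conv_layers = as.integer(conv_layers),
                 filter_size = as.integer(filter_size),
                 filter_skip = as.integer(filter_skip),
                 base_kernels = as.integer(base_kernels),
                 dropout_rate = dropout_rate),
            class = "nn_spec")
}

#' Output length of a valid strided 1-D convolution
#'
#' `floor((len_in - filter_size) / stride) + 1`; an architecture is invalid
#' when any layer's output length falls below 1.
#'
#' @param len_in input length.
#' @param filter_size,stride filter taps and skip.
#' @return Integer output length (possibly < 1 for invalid geometry).
#' @export
conv_output_length <- function(len_in, filter_size, stride) {
  floor((len_in - filter_size) / stride) + 1
}

lecun_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
}

init_params <- function(spec, d_in) {
  if (spec$family == "fnn") {
    sizes <- c(d_in, rep(spec$neurons, spec$depth))
    layers <- lapply(seq_len(spec$depth), function(i)
      list(W = lecun_mat(sizes[i], sizes[i + 1]), b = numeric(sizes[i + 1])))
    list(layers = layers, Wo = lecun_mat(spec$neurons, 2), bo = numeric(2))
  } else if (spec$family == "rnn") {
    m <- ceiling(d_in / spec$partitions)
    lf <- spec$neurons_per_fold
    list(Wx = lecun_mat(m, lf), Wh = lecun_mat(lf, lf), br = numeric(lf),
         Wf = lecun_mat(lf, spec$neurons), bf = numeric(spec$neurons),
         Wo = lecun_mat(spec$neurons, 2), bo = numeric(2))
  } else {
    len <- d_in; cin <- 1
    conv <- vector("list", spec$conv_layers)
    for (j in seq_len(spec$conv_layers)) {
      cout <- spec$base_kernels * 2^(j - 1)
      len <- conv_output_length(len, spec$filter_size, spec$filter_skip)
      if (len < 1) {
        stop("invalid CNN architecture: layer ", j,
             " output length below 1", call. = FALSE)
      }
      conv[[j]] <- list(K = lecun_mat(spec$filter_size * cin, cout),
                        b = numeric(cout))
      cin <- cout
    }
    flat <- len * cin
    list(conv = conv, Wf = lecun_mat(flat, spec$neurons),
         bf = numeric(spec$neurons), Wo = lecun_mat(spec$neurons, 2),
         bo = numeric(2))
  }
}

# alpha-dropout transform; returns output and the slope (a * mask)
alpha_dropout <- function(h, p_drop) {
  q <- 1 - p_drop
  ap <- -SELU_LAMBDA * SELU_ALPHA
  a <- (q + ap^2 * q * (1 - q))^(-0.5)
  b <- -a * (1 - q) * ap
  keep <- stats::runif(length(h)) < q
  list(out = a * (h * keep + ap * (!keep)) + b, slope = a * keep)
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Forward pass of a network
#'
#' Runs one z-scored input spectrum through the architecture described by
#' `spec` and returns the two-unit softmax output `(benign, malignant)`.
#' Alpha-dropout fires only when `training = TRUE` (it draws from the R
#' random stream); inference is deterministic.
#'
#' @param params parameter list created by the trainer.
#' @param spec an [nn_spec()].
#' @param x numeric input vector.
#' @param training logical; enables dropout.
#' @return List with `prob` (length-2, sums to 1) and `cache` for
#'   backpropagation.
#' @export
forward_nn_pass <- function(params, spec, x, training = FALSE) {
  p_drop <- if (training) spec$dropout_rate else 0
  if (spec$family == "fnn") {
    hs <- list(); zs <- list(); slopes <- list()
    h <- x
    for (i in seq_along(params$layers)) {
      z <- drop(h %*% params$layers[[i]]$W) + params$layers[[i]]$b
      a <- selu(z)
      if (p_drop > 0) {
        d <- alpha_dropout(a, p_drop); a <- d$out; slopes[[i]] <- d$slope
      } else slopes[[i]] <- rep(1, length(a))
      zs[[i]] <- z; hs[[i]] <- a
      h <- a
    }
    logits <- drop(h %*% params$Wo) + params$bo
    list(prob = softmax2(logits),
         cache = list(x = x, zs = zs, hs = hs, slopes = slopes))
  } else if (spec$family == "rnn") {
    chunks <- partition_input(x, spec$partitions)
    lf <- length(params$br)
    hprev <- numeric(lf)
    zs <- matrix(0, lf, spec$partitions)
    hsr <- matrix(0, lf, spec$partitions)
    for (t in seq_len(spec$partitions)) {
      z <- drop(chunks[, t] %*% params$Wx) + drop(hprev %*% params$Wh) +
        params$br
      hprev <- selu(z)
      zs[, t] <- z; hsr[, t] <- hprev
    }
    zf <- drop(hprev %*% params$Wf) + params$bf
    hf <- selu(zf)
    if (p_drop > 0) {
      d <- alpha_dropout(hf, p_drop); hf2 <- d$out; slope <- d$slope
    } else { hf2 <- hf; slope <- rep(1, length(hf)) }
    logits <- drop(hf2 %*% params$Wo) + params$bo
    list(prob = softmax2(logits),
         cache = list(chunks = chunks, zs = zs, hsr = hsr, zf = zf,
                      hf2 = hf2, slope = slope))
  } else {
    h <- matrix(x, ncol = 1)               # length x channels
    caches <- list()
    for (j in seq_along(params$conv)) {
      cv <- params$conv[[j]]
      M <- im2col(h, spec$filter_size, spec$filter_skip)
      Z <- sweep(M %*% cv$K, 2, cv$b, "+")
      H <- selu(Z)
      caches[[j]] <- list(M = M, Z = Z, len_in = nrow(h))
      h <- H
    }
    flat <- as.vector(h)
    zf <- drop(flat %*% params$Wf) + params$bf
    hf <- selu(zf)
    if (p_drop > 0) {
      d <- alpha_dropout(hf, p_drop); hf2 <- d$out; slope <- d$slope
    } else { hf2 <- hf; slope <- rep(1, length(hf)) }
    logits <- drop(hf2 %*% params$Wo) + params$bo
    list(prob = softmax2(logits),
         cache = list(conv = caches, flat = flat, hdim = dim(h), zf = zf,
                      hf2 = hf2, slope = slope))
  }
}

# patches-as-rows matrix of a (length x channels) input
im2col <- function(h, f, s) {
  L <- nrow(h); C <- ncol(h)
  n_out <- conv_output_length(L, f, s)
  idx <- outer(seq_len(f), (seq_len(n_out) - 1) * s, "+")  # f x n_out
  M <- matrix(0, n_out, f * C)
  for (c in seq_len(C)) {
    M[, (c - 1) * f + seq_len(f)] <- t(matrix(h[idx, c], nrow = f))
  }
  M
}

col2im <- function(dM, L, C, f, s) {
  n_out <- nrow(dM)
  dh <- matrix(0, L, C)
  idx <- outer(seq_len(f), (seq_len(n_out) - 1) * s, "+")
  for (c in seq_len(C)) {
    patch <- t(dM[, (c - 1) * f + seq_len(f), drop = FALSE])  # f x n_out
    for (p in seq_len(n_out)) {
      dh[idx[, p], c] <- dh[idx[, p], c] + patch[, p]
    }
  }
  dh
}

# gradients of the BCE loss w.r.t. every parameter; y in {0, 1}
backward_nn_pass <- function(params, spec, cache, prob, y) {
  dlog <- (prob[2] - y) * c(-1, 1)         # d loss / d logits
  if (spec$family == "fnn") {
    nl <- length(params$layers)
    h_last <- if (nl > 0) cache$hs[[nl]] else cache$x
    gWo <- outer(h_last, dlog)
    gbo <- dlog
    dh <- drop(params$Wo %*% dlog)
    glayers <- vector("list", nl)
    for (i in rev(seq_len(nl))) {
      dz <- dh * cache$slopes[[i]] * selu_grad(cache$zs[[i]])
      input <- if (i > 1) cache$hs[[i - 1]] else cache$x
      glayers[[i]] <- list(W = outer(input, dz), b = dz)
      dh <- drop(params$layers[[i]]$W %*% dz)
    }
    list(layers = glayers, Wo = gWo, bo = gbo)
  } else if (spec$family == "rnn") {
    gWo <- outer(cache$hf2, dlog); gbo <- dlog
    dhf <- drop(params$Wo %*% dlog) * cache$slope * selu_grad(cache$zf)
    h_last <- cache$hsr[, spec$partitions]
    gWf <- outer(h_last, dhf); gbf <- dhf
    dh <- drop(params$Wf %*% dhf)
    gWx <- array(0, dim(params$Wx)); gWh <- array(0, dim(params$Wh))
    gbr <- numeric(length(params$br))
    for (t in rev(seq_len(spec$partitions))) {
      dz <- dh * selu_grad(cache$zs[, t])
      gWx <- gWx + outer(cache$chunks[, t], dz)
      hp <- if (t > 1) cache$hsr[, t - 1] else numeric(length(dz))
      gWh <- gWh + outer(hp, dz)
      gbr <- gbr + dz
      dh <- drop(params$Wh %*% dz)
    }
    list(Wx = gWx, Wh = gWh, br = gbr, Wf = gWf, bf = gbf, Wo = gWo,
         bo = gbo)
  } else {
    gWo <- outer(cache$hf2, dlog); gbo <- dlog
    dhf <- drop(params$Wo %*% dlog) * cache$slope * selu_grad(cache$zf)
    gWf <- outer(cache$flat, dhf); gbf <- dhf
    dflat <- drop(params$Wf %*% dhf)
    dH <- matrix(dflat, cache$hdim[1], cache$hdim[2])
    gconv <- vector("list", length(params$conv))
    for (j in rev(seq_along(params$conv))) {
      cc <- cache$conv[[j]]
      dZ <- dH * selu_grad(cc$Z)
      gconv[[j]] <- list(K = crossprod(cc$M, dZ), b = colSums(dZ))
      dM <- dZ %*% t(params$conv[[j]]$K)
      cin <- nrow(params$conv[[j]]$K) / spec$filter_size
      dH <- col2im(dM, cc$len_in, cin, spec$filter_size, spec$filter_skip)
    }
    list(conv = gconv, Wf = gWf, bf = gbf, Wo = gWo, bo = gbo)
  }
}

## ---- flat parameter views (used by the finite-difference checks) -------

#' Flat views of network parameters
#'
#' Serialise a nested parameter list to one numeric vector and back
#' (depth-first order), used by the finite-difference gradient checks.
#'
#' @param params,template nested parameter list.
#' @param vec numeric vector of the same total length.
#' @return A numeric vector, or a parameter list shaped like `template`.
#' @export
flatten_params <- function(params) {
  unlist(rapply(params, function(v) if (is.numeric(v)) as.vector(v),
                how = "list"), use.names = FALSE)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(vec, template) {
  i <- 0
  rapply(template, function(v) {
    if (!is.numeric(v)) return(v)
    n <- length(v)
    out <- vec[i + seq_len(n)]
    i <<- i + n
    if (!is.null(dim(v))) dim(out) <- dim(v)
    out
  }, how = "replace")
}

adagrad_update <- function(params, grads, accum, lr, eps) {
  walk <- function(p, g, a) {
    if (is.list(p)) {
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], a[[k]])
        p[[k]] <- r$p; a[[k]] <- r$a
      }
    } else if (is.numeric(p)) {
      a <- a + g^2
      p <- p - lr * g / (sqrt(a) + eps)
    }
    list(p = p, a = a)
  }
  walk(params, grads, accum)
}

#' A single AdaGrad step on one parameter block
#'
#' Accumulates the squared gradient (`G <- G + g^2`) and moves the
#' parameter by `-lr * g / (sqrt(G) + eps)`, elementwise.
#'
#' @param value,grad,accum parameter, gradient and accumulator (same shape).
#' @param lr,eps learning rate and stabilising constant.
#' @return List with updated `value` and `accum`.
#' @export
adagrad_step <- function(value, grad, accum, lr, eps) {
  accum <- accum + grad^2
  list(value = value - lr * grad / (sqrt(accum) + eps), accum = accum)
}

zero_like <- function(params) {
  rapply(params, function(v) if (is.numeric(v)) v * 0 else v,
         how = "replace")
}

#' Train a self-normalising neural network
#'
#' Per-sample stochastic gradient descent with AdaGrad for `spec$epochs`
#' epochs (shuffled each epoch) on binary cross-entropy; weights start from
#' a Gaussian with SD `1/sqrt(fan_in)` (the standard companion of SELU) and
#' biases from zero.  Inputs are expected z-score normalised per spectrum.
#'
#' @param spec an [nn_spec()].
#' @param train,val [ftir_dataset()]s; validation is only scored, never
#'   trained on.
#' @param seed optional integer seed making the whole run bit-reproducible.
#' @return An `ftir_classifier` (kind `"nn"`) with the common
#'   probability-of-malignancy contract.
#' @export
train_network <- function(spec, train, val = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- spectra_matrix(train); y <- label01(train$label)
  params <- init_params(spec, ncol(x))
  accum <- zero_like(params)
  for (e in seq_len(spec$epochs)) {
    for (i in sample.int(nrow(x))) {
      fw <- forward_nn_pass(params, spec, x[i, ], training = TRUE)
      g <- backward_nn_pass(params, spec, fw$cache, fw$prob, y[i])
      upd <- adagrad_update(params, g, accum, spec$learning_rate,
                            spec$adagrad_epsilon)
      params <- upd$p; accum <- upd$a
    }
  }
  pm <- list(params = params, spec = spec)
  cl <- new_classifier("nn", pm)
  cl$train_accuracy <- accuracy_at_half(predict_nn(pm, x), y)
  if (!is.null(val)) {
    cl$val_accuracy <- accuracy_at_half(predict_nn(pm, spectra_matrix(val)),
                                        label01(val$label))
  }
  cl
}

predict_nn <- function(pm, x) {
  apply(x, 1, function(r)
    forward_nn_pass(pm$params, pm$spec, r, training = FALSE)$prob[2])
}

# loss of one sample as a function of flat parameters (finite differences)
nn_loss_flat <- function(vec, template, spec, x, y) {
  p <- unflatten_params(vec, template)
  bce_loss(forward_nn_pass(p, spec, x, training = FALSE)$prob[2], y)
}
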