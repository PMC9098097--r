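test_that("SELU has the self-normalising constants and limits", {
  lambda <- 1.05070098
  alpha <- 1.67326324
  expect_equal(selu(0), 0)
  expect_equal(selu(1), lambda, tolerance = 1e-7)
  expect_equal(selu(-50), -lambda * alpha, tolerance = 1e-6)
  expect_equal(selu(-50), -1.758099, tolerance = 1e-5)
  # derivative consistency
  h <- 1e-6
  for (x in c(-1.3, -0.1, 0.4, 2)) {
    expect_equal(selu_grad(x), (selu(x + h) - selu(x - h)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("binary cross-entropy has the expected values", {
  expect_equal(bce_loss(1, "malignant"), 0, tolerance = 1e-10)
  expect_equal(bce_loss(0.5, "malignant"), log(2))
  expect_equal(bce_loss(0.5, "benign"), log(2))
  expect_gt(bce_loss(0, "malignant"), 20)   # clipped, finite
})

test_that("input partitioning pads the last chunk with zeros", {
  x <- seq_len(462)
  ch <- partition_input(x, 10)
  expect_equal(dim(ch), c(47, 10))
  expect_equal(sum(ch[, 10] == 0), 8)
  expect_equal(as.vector(ch)[seq_along(x)], x)
  expect_equal(as.vector(partition_input(x, 1)), x)
  expect_error(partition_input(1:3, 5), "between 1 and")
})

test_that("AdaGrad steps follow the accumulator arithmetic", {
  s <- adagrad_step(1, 2, 0, lr = 0.1, eps = 1e-12)
  expect_equal(s$accum, 4)
  expect_equal(s$value, 1 - 0.1 * 2 / 2, tolerance = 1e-9)
  s0 <- adagrad_step(1, 0, 3, lr = 0.1, eps = 1e-8)
  expect_equal(s0$value, 1)
  expect_equal(s0$accum, 3)
  # repeated identical gradients shrink the step as 1/sqrt(t)
  v <- 0; a <- 0; steps <- numeric(5)
  for (t in 1:5) {
    s <- adagrad_step(v, 1, a, lr = 1, eps = 0)
    steps[t] <- abs(s$value - v); v <- s$value; a <- s$accum
  }
  expect_equal(steps, 1 / sqrt(1:5), tolerance = 1e-12)
})

test_that("softmax heads normalise and zero networks output one half", {
  spec <- nn_spec("fnn", depth = 2, neurons = 4, dropout_rate = 0)
  params <- ftirlung:::init_params(spec, 10)
  zeroed <- unflatten_params(0 * flatten_params(params), params)
  out <- forward_nn_pass(zeroed, spec, rnorm(10))
  expect_equal(out$prob, c(0.5, 0.5))
  set.seed(51)
  for (i in 1:5) {
    out <- forward_nn_pass(params, spec, rnorm(10))
    expect_equal(sum(out$prob), 1, tolerance = 1e-12)
  }
  # inference is deterministic (dropout off)
  x <- rnorm(10)
  spec9 <- nn_spec("fnn", depth = 2, neurons = 4, dropout_rate = 0.9)
  p1 <- forward_nn_pass(params, spec9, x, training = FALSE)$prob
  p2 <- forward_nn_pass(params, spec9, x, training = FALSE)$prob
  expect_identical(p1, p2)
})

test_that("analytic gradients match central finite differences", {
  grad_check <- function(spec, d_in, seed) {
    set.seed(seed)
    x <- rnorm(d_in); y <- 1L
    params <- ftirlung:::init_params(spec, d_in)
    fw <- forward_nn_pass(params, spec, x)
    ga <- flatten_params(
      ftirlung:::backward_nn_pass(params, spec, fw$cache, fw$prob, y))
    v0 <- flatten_params(params)
    h <- 1e-5
    gn <- vapply(seq_along(v0), function(i) {
      vp <- v0; vp[i] <- vp[i] + h
      vm <- v0; vm[i] <- vm[i] - h
      (ftirlung:::nn_loss_flat(vp, params, spec, x, y) -
         ftirlung:::nn_loss_flat(vm, params, spec, x, y)) / (2 * h)
    }, numeric(1))
    max(abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6))
  }
  expect_lt(grad_check(nn_spec("fnn", depth = 2, neurons = 3,
                               dropout_rate = 0), 7, 1), 1e-5)
  expect_lt(grad_check(nn_spec("rnn", partitions = 3, neurons_per_fold = 2,
                               neurons = 3, dropout_rate = 0), 7, 2), 1e-5)
  expect_lt(grad_check(nn_spec("cnn", conv_layers = 1, filter_size = 3,
                               filter_skip = 2, base_kernels = 2,
                               neurons = 3, dropout_rate = 0), 9, 3), 1e-5)
})

test_that("convolution shapes follow the strided-length rule", {
  expect_equal(conv_output_length(462, 8, 4), 114)
  # brute-force shape simulation across geometries
  for (f in c(2, 5, 11)) {
    for (s in c(2, 3, f)) {
      for (L in c(12, 30)) {
        positions <- 0
        p <- 1
        while (p + f - 1 <= L) { positions <- positions + 1; p <- p + s }
        expect_equal(conv_output_length(L, f, s), positions)
      }
    }
  }
  spec_bad <- nn_spec("cnn", conv_layers = 5, filter_size = 11,
                      filter_skip = 11, base_kernels = 2, neurons = 3)
  expect_error(ftirlung:::init_params(spec_bad, 30), "invalid CNN")
})

test_that("training learns separable data and is seed-reproducible", {
  d <- blob_dataset(8, p = 6, sep = 5, seed = 52)
  z <- zscore_normalize(d)
  spec <- nn_spec("fnn", epochs = 60, neurons = 4, depth = 2,
                  learning_rate = 0.05, dropout_rate = 0)
  wins <- vapply(1:6, function(s)
    train_network(spec, z, seed = s)$train_accuracy, numeric(1))
  expect_gte(mean(wins == 1), 5 / 6)
  # untrained network sits at chance on balanced label-free data
  set.seed(99)
  d0 <- toy_dataset(matrix(rnorm(16 * 6), 16),
                    labels = rep(c("malignant", "benign"), 8),
                    grid = tiny_grid(6))
  spec0 <- nn_spec("fnn", epochs = 0, neurons = 4, depth = 2)
  acc0 <- vapply(1:10, function(s)
    train_network(spec0, d0, seed = s)$train_accuracy, numeric(1))
  expect_lt(abs(mean(acc0) - 0.5), 0.2)
  # bit-identical refit from the same seed
  a <- train_network(spec, z, seed = 11)
  b <- train_network(spec, z, seed = 11)
  expect_identical(flatten_params(a$params$params),
                   flatten_params(b$params$params))
})

test_that("deep SELU stacks keep activations near zero mean, unit var", {
  set.seed(53)
  spec <- nn_spec("fnn", depth = 8, neurons = 24, dropout_rate = 0)
  params <- ftirlung:::init_params(spec, 60)
  stats_l <- matrix(0, 100, 2)
  for (r in 1:100) {
    x <- rnorm(60)
    fw <- forward_nn_pass(params, spec, x)
    h8 <- fw$cache$hs[[8]]
    stats_l[r, ] <- c(mean(h8), stats::var(h8))
  }
  expect_lt(abs(mean(stats_l[, 1])), 0.25)
  expect_lt(abs(mean(stats_l[, 2]) - 1), 0.6)
})
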