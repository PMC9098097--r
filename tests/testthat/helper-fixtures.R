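# Shared fixtures, all generated in code.

# small equispaced descending grid inside the fingerprint region
tiny_grid <- function(n = 24, high = 1700, low = 900) {
  seq(high, low, length.out = n)
}

# dataset with a hand-set matrix on a tiny grid
toy_dataset <- function(m, labels = NULL, grid = NULL) {
  grid <- grid %||% tiny_grid(ncol(m))
  ftirlung::ftir_dataset(m, grid, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two well-separated Gaussian blobs in p dimensions, as a z-scored-like
# numeric dataset (classes differ in the first two coordinates)
blob_dataset <- function(n_per_class = 10, p = 6, sep = 4, seed = 1,
                         noise = 0.5) {
  set.seed(seed)
  m <- rbind(
    matrix(stats::rnorm(n_per_class * p, 0, noise), n_per_class),
    matrix(stats::rnorm(n_per_class * p, 0, noise), n_per_class))
  m[seq_len(n_per_class), 1:2] <- m[seq_len(n_per_class), 1:2] + sep
  toy_dataset(m, labels = rep(c("malignant", "benign"), each = n_per_class),
              grid = tiny_grid(p))
}

# reduced-scale band model + cohort for quick end-to-end runs
desk_grid <- function() seq(1800, 850, length.out = 120)

desk_cohort <- function(n_m = 18, n_b = 22, seed = 1, model = band_model()) {
  ftirlung::simulate_cohort(n_m, n_b, model = model, grid = desk_grid(),
                            seed = seed)
}

# compact nn specs for quick training
desk_nn_specs <- function(epochs = 15) {
  list(
    fnn2 = nn_spec("fnn", epochs = epochs, neurons = 6, depth = 2,
                   learning_rate = 1e-2),
    fnn4 = nn_spec("fnn", epochs = epochs, neurons = 6, depth = 4,
                   learning_rate = 1e-2),
    fnn8 = nn_spec("fnn", epochs = epochs, neurons = 6, depth = 8,
                   learning_rate = 1e-2),
    rnn = nn_spec("rnn", epochs = epochs, partitions = 8,
                  neurons_per_fold = 6, neurons = 6, learning_rate = 1e-2),
    cnn = nn_spec("cnn", epochs = epochs, conv_layers = 1, filter_size = 5,
                  filter_skip = 3, base_kernels = 2, neurons = 6,
                  learning_rate = 1e-2))
}

subset_ds <- function(data, idx) {
  out <- data[idx, ]
  class(out) <- class(data)
  out
}
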