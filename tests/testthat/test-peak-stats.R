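test_that("median spectrum equals a sort-based oracle", {
  m <- rbind(c(1, 5, 2), c(2, 6, 9), c(9, 7, 4))
  d <- toy_dataset(m, labels = rep("malignant", 3), grid = tiny_grid(3))
  expect_equal(unname(median_spectrum(d, "malignant")), c(2, 6, 4))
  # single spectrum is its own median
  d1 <- toy_dataset(m[1, , drop = FALSE], labels = "benign",
                    grid = tiny_grid(3))
  expect_equal(unname(median_spectrum(d1, "benign")), c(1, 5, 2))
  expect_error(median_spectrum(d1, "malignant"), "no spectra")
  # random data vs apply/sort oracle
  set.seed(1)
  mm <- matrix(rnorm(60), 5)
  dd <- toy_dataset(mm, labels = rep("benign", 5), grid = tiny_grid(12))
  oracle <- vapply(seq_len(12), function(j) sort(mm[, j])[3], numeric(1))
  expect_equal(unname(median_spectrum(dd, "benign")), oracle)
})

test_that("peak detection finds single bands and the nine-band template", {
  g <- default_grid()
  one <- exp(-(g - 1200)^2 / (2 * 15^2))
  pk <- detect_peaks(one, g, 0.02)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$wavenumber - 1200), diff(range(g)) / 461 + 1e-9)
  # noiseless malignant template: nine peaks near the tabulated positions
  tpl <- class_template("malignant", band_model(baseline_amplitude = 0,
                                                noise_sd = 0), g)
  pk9 <- detect_peaks(tpl, g, 0.02)
  expect_equal(nrow(pk9), 9)
  printed <- c(1636, 1537, 1452, 1401, 1314, 1236, 1160, 1051, 880)
  step <- diff(range(g)) / 461
  expect_true(all(abs(pk9$wavenumber - printed) <= 2 * step))
})

test_that("peak detection equals a brute-force prominence scan", {
  brute <- function(y, minp) {
    n <- length(y)
    peaks <- integer()
    for (i in 2:(n - 1)) {
      if (!(y[i] > y[i - 1] && y[i] > y[i + 1])) next
      lm <- Inf; j <- i - 1
      while (j >= 1 && y[j] <= y[i]) { lm <- min(lm, y[j]); j <- j - 1 }
      rm <- Inf; j <- i + 1
      while (j <= n && y[j] <= y[i]) { rm <- min(rm, y[j]); j <- j + 1 }
      l2 <- if (is.finite(lm)) lm else -Inf
      r2 <- if (is.finite(rm)) rm else -Inf
      base <- max(l2, r2)
      if (!is.finite(base)) base <- min(y)
      if (y[i] - base >= minp) peaks <- c(peaks, i)
    }
    peaks
  }
  set.seed(7)
  for (k in 1:10) {
    y <- as.numeric(stats::filter(rnorm(120), rep(1 / 5, 5),
                                  sides = 2))
    y[is.na(y)] <- 0
    w <- seq(1790, 860, length.out = 120)
    got <- detect_peaks(y, w, 0.1)$wavenumber
    want <- w[brute(y, 0.1)]
    expect_equal(sort(got), sort(want))
  }
})

test_that("Mann-Whitney exact enumeration matches hand results", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
})

test_that("Mann-Whitney large-sample p agrees with the reference", {
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(15 + k); y <- rnorm(18, 0.4)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_lt(abs(ours$p - ref$p.value), 1e-6)
  }
  # tie correction path
  x <- rep(1:5, 3); y <- rep(2:6, 3)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_lt(abs(mann_whitney_u(x, y)$p - ref$p.value), 1e-6)
})

test_that("Shapiro-Wilk gate behaves under null and alternative", {
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  set.seed(12)
  x <- rnorm(100)
  s <- shapiro_wilk(x)
  expect_true(s$W > 0 && s$W <= 1)
  # affine invariance
  s2 <- shapiro_wilk(5 - 3 * x)
  expect_equal(s$W, s2$W, tolerance = 1e-12)
  # skewed samples are rejected far more often than normal ones
  pn <- vapply(1:40, function(i) { set.seed(i); shapiro_wilk(rnorm(100))$p },
               numeric(1))
  pe <- vapply(1:40, function(i) { set.seed(i); shapiro_wilk(rexp(100))$p },
               numeric(1))
  expect_gte(mean(pn > 0.05), 0.9)
  expect_gte(mean(pe < 0.05), 0.95)
})

test_that("the band table recovers programmed group differences", {
  d <- simulate_cohort(53, 65, seed = 21)
  tab <- build_peak_table(peak_normalize(d))
  # the amide II pair is detected near its printed positions and significant
  amide2 <- tab[which.min(abs(tab$pos_malignant - 1537)), ]
  expect_lt(abs(amide2$pos_malignant - 1537), 6)
  expect_true(amide2$significant)
  # glycogen pair: positions 21 cm^-1 apart must still pair
  gly <- tab[which.min(abs(tab$pos_malignant - 1051)), ]
  expect_false(is.na(gly$pos_benign))
  expect_true(gly$significant)
})

test_that("the band table is invariant to sample order", {
  d <- simulate_cohort(10, 12, seed = 22, grid = desk_grid())
  pn <- peak_normalize(d)
  t1 <- build_peak_table(pn)
  set.seed(1)
  perm <- sample(n_spectra(pn))
  t2 <- build_peak_table(subset_ds(pn, perm))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("a class-identical generator stays at the nominal error rate", {
  sig <- vapply(1:25, function(s) {
    d <- simulate_cohort(12, 14, model = null_band_model(),
                         grid = desk_grid(), seed = 300 + s)
    tab <- build_peak_table(peak_normalize(d))
    mean(tab$significant)
  }, numeric(1))
  expect_lt(mean(sig), 0.15)
})
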