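test_that("spectrum constructor enforces its invariants", {
  g <- tiny_grid()
  expect_s3_class(spectrum(g, rep(1, 16)), "lss_spectrum")
  expect_error(spectrum(g[1], 1), "at least 2")
  expect_error(spectrum(g, rep(1, 15)), "equal length")
  expect_error(spectrum(rev(g), rep(1, 16)), "strictly increasing")
  expect_error(spectrum(g, c(rep(1, 15), -1)), "non-negative")
  expect_error(spectrum(g, rep(1, 16), fiber_id = "R9"), "fiber_id")
  expect_error(spectrum(g, rep(1, 16), construct_label = "2222"), "label")
})

test_that("default grid spans 500-1100 nm and matches the kernel-width anchor", {
  g <- default_wavelength_grid()
  expect_length(g, 3587L)
  expect_equal(range(g), c(500, 1100))
  # 20-sample Gaussian kernel stddev corresponds to ~3.3 nm at this spacing
  expect_equal(20 * diff(g)[1], 3.3, tolerance = 0.02)
})

test_that("mean normalization divides by the mean and is idempotent", {
  s <- flat_spectrum(2)
  expect_equal(mean_normalize(s)$intensities, rep(1, 16))
  s2 <- spectrum(tiny_grid(2), c(1, 3))
  expect_equal(mean_normalize(s2)$intensities, c(0.5, 1.5))
  set.seed(42)
  for (i in 1:20) {
    s3 <- spectrum(tiny_grid(), runif(16, 0.1, 5), fiber_id = "R2",
                   construct_label = "11110000", rebuild_id = 7L)
    n1 <- mean_normalize(s3)
    expect_equal(mean(n1$intensities), 1, tolerance = 1e-9)
    expect_equal(mean_normalize(n1)$intensities, n1$intensities,
                 tolerance = 1e-9)
  }
  expect_identical(mean_normalize(s3)$meta, s3$meta)
  expect_error(mean_normalize(flat_spectrum(0)), "positive")
})

test_that("calibration divides by the reference and re-normalizes", {
  s <- spectrum(tiny_grid(2), c(1, 1))
  ref <- spectrum(tiny_grid(2), c(0.5, 1.5))
  expect_equal(calibrate(s, ref)$intensities, c(1.5, 0.5))
  # self-calibration gives a flat unit spectrum for any valid input
  set.seed(7)
  for (i in 1:10) {
    x <- mean_normalize(spectrum(tiny_grid(), runif(16, 0.2, 3)))
    expect_equal(calibrate(x, x)$intensities, rep(1, 16), tolerance = 1e-12)
  }
  bad_ref <- spectrum(tiny_grid(2), c(0, 1))
  expect_error(calibrate(s, bad_ref), "positive")
  other_grid <- spectrum(tiny_grid(2) + 1, c(1, 1))
  expect_error(calibrate(s, other_grid), "grid")
})

test_that("pearson correlation matches the direct formula and its symmetries", {
  g3 <- default_wavelength_grid(3)
  x <- spectrum(g3, c(1, 2, 3))
  y <- spectrum(g3, c(1, 2, 4))
  expect_equal(pearson_correlation(x, y),
               brute_force_pearson(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x), 1.0)
  y_neg <- spectrum(g3, max(x$intensities) - x$intensities + 1)
  expect_equal(pearson_correlation(x, y_neg), -1.0)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    a <- runif(n); b <- runif(n)
    sa <- spectrum(default_wavelength_grid(n), a)
    sb <- spectrum(default_wavelength_grid(n), b)
    expect_equal(pearson_correlation(sa, sb), brute_force_pearson(a, b),
                 tolerance = 1e-12)
    expect_equal(pearson_correlation(sa, sb), pearson_correlation(sb, sa))
    # invariant under positive affine rescaling
    sc <- spectrum(default_wavelength_grid(n), 2.5 * a + 1)
    expect_equal(pearson_correlation(sc, sb), pearson_correlation(sa, sb),
                 tolerance = 1e-9)
  }
  expect_error(pearson_correlation(flat_spectrum(1), flat_spectrum(2)),
               "zero variance")
})

test_that("SNR recovers mean/sigma on simulated replicates and is scale-invariant", {
  set.seed(3)
  m <- 10; sigma <- 0.5
  reps <- lapply(1:100, function(i) {
    spectrum(tiny_grid(64), pmax(m + rnorm(64, sd = sigma), 0))
  })
  snr <- compute_snr(reps)
  expect_equal(snr, m / sigma, tolerance = 0.1 * m / sigma)
  scaled <- lapply(reps, function(s) with_intensities_test(s, 3 * s$intensities))
  expect_equal(compute_snr(scaled), snr, tolerance = 1e-12)
  # identical replicates have no noise: infinite-SNR sentinel
  s <- flat_spectrum(2)
  expect_warning(out <- compute_snr(list(s, s)), "identical")
  expect_identical(out, Inf)
  expect_error(compute_snr(list(s)), "2")
})

test_that("smoothed difference curves are zero for self-comparison and conserve spike area", {
  set.seed(5)
  group <- lapply(1:4, function(i) {
    mean_normalize(spectrum(tiny_grid(101), runif(101, 0.5, 1.5)))
  })
  out <- smoothed_difference(group, group)
  expect_length(out$mean, 101)
  expect_true(all(abs(out$mean) < 1e-12))
  # a single-sample spike smooths to a Gaussian bump with the same area
  base <- rep(1, 101)
  spike <- base; spike[51] <- 1 + 5
  g_base <- list(spectrum(tiny_grid(101), base))
  g_spike <- list(spectrum(tiny_grid(101), spike))
  sm <- smoothed_difference(g_spike, g_base, kernel_stddev_samples = 3)
  expect_equal(sum(sm$mean), 5, tolerance = 1e-6)
  expect_equal(which.max(sm$mean), 51)
  # the smoothed bump matches the discrete Gaussian kernel itself
  expect_equal(sm$mean[51], 5 * dnorm(0, sd = 3) / sum(dnorm(-12:12, sd = 3)),
               tolerance = 1e-6)
  expect_error(smoothed_difference(list(), group), "non-empty")
})

test_that("fiber concatenation orders by fiber index and validates pairing", {
  g <- tiny_grid()
  mk <- function(fiber, rebuild = 1L) {
    mean_normalize(spectrum(g, runif(16, 0.5, 1.5), fiber_id = fiber,
                            construct_label = "11110000",
                            rebuild_id = rebuild))
  }
  set.seed(2)
  s1 <- mk("R5"); s2 <- mk("R1")
  fv <- concatenate_fiber_spectra(s1, s2)
  expect_s3_class(fv, "lss_features")
  expect_identical(fv$source_fibers, c("R1", "R5"))
  expect_length(fv$values, 32L)
  expect_equal(fv$values, c(s2$intensities, s1$intensities))
  expect_error(concatenate_fiber_spectra(s1, mk("R5")), "itself")
  expect_error(concatenate_fiber_spectra(s1, mk("R1", rebuild = 2L)),
               "rebuild")
  raw <- spectrum(g, runif(16, 0.5, 1.5) * 3, fiber_id = "R1",
                  construct_label = "11110000", rebuild_id = 1L)
  expect_error(concatenate_fiber_spectra(s1, raw), "normalized")
})
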