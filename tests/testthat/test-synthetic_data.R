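norm_int <- function(s) s$intensities / mean(s$intensities)

test_that("modal sampling depth follows the banana-path closed form", {
  geom <- fiber_geometry()
  expect_equal(depth_sensitivity(geom$r_sd_um),
               geom$r_sd_um / (2 * sqrt(2)), tolerance = 1e-9)
  expect_equal(depth_sensitivity(0), 0)
  expect_error(depth_sensitivity(-1), "non-negative")
  expect_true(all(diff(geom$r_sd_um) > 0))
})

test_that("layer weights are a normalized kernel that deepens with fiber distance", {
  mod <- tiny_model()
  W <- t(vapply(paste0("R", 1:5), layer_weights, numeric(8), model = mod))
  expect_equal(unname(rowSums(W)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(W > 0))
  # argmax layer depth is non-decreasing from R1 to R5
  expect_true(all(diff(apply(W, 1, which.max)) >= 0))
  # direct evaluation of the kernel for R5 matches the implementation
  geom <- fiber_geometry()
  decay <- mod$sensitivity_decay * (750 / 210)^mod$decay_separation_exponent
  w_ref <- exp(-abs((1:8 - 0.5) * 200 - 750 / (2 * sqrt(2))) / decay)
  expect_equal(layer_weights("R5", mod), w_ref / sum(w_ref), tolerance = 1e-12)
  # an extremely wide kernel approaches uniform weights 1/8
  wide <- tissue_optical_model(tiny_grid(), sensitivity_decay = 1e9,
                               decay_separation_exponent = 0)
  expect_equal(layer_weights("R2", wide), rep(1 / 8, 8), tolerance = 1e-6)
  expect_error(layer_weights("R7", mod), "unknown")
})

test_that("noise-free spectra are the depth-weighted tissue mixture", {
  mod <- noise_free_model()
  for (f in c("R1", "R4")) {
    s_myo <- simulate_spectrum("00000000", f, mod)
    # pure construct: proportional to lamp x tissue base
    expect_equal(norm_int(s_myo),
                 local({
                   v <- mod$lamp_spectrum * mod$base_spectrum_myocardium
                   v / mean(v)
                 }), tolerance = 1e-12)
    # pointwise ratio of the pure constructs is the base-spectrum ratio
    s_ao <- simulate_spectrum("11111111", f, mod)
    expect_equal(s_ao$intensities / s_myo$intensities,
                 mod$base_spectrum_aorta / mod$base_spectrum_myocardium,
                 tolerance = 1e-12)
  }
  # two-tissue construct equals the hand-computed two-term mixture
  w <- layer_weights("R3", mod)
  wa <- sum(w[1:4])
  mix <- mod$lamp_spectrum * (wa * mod$base_spectrum_aorta +
                                (1 - wa) * mod$base_spectrum_myocardium) *
    (210 / 480)^mod$amplitude_exponent
  expect_equal(simulate_spectrum("11110000", "R3", mod)$intensities, mix,
               tolerance = 1e-12)
})

test_that("reference standard reflects 99% of the lamp and calibration removes the lamp", {
  mod <- noise_free_model()
  ref <- reference_spectrum(mod)
  expect_identical(ref$meta$fiber_id, "standard")
  expect_equal(ref$intensities, 0.99 * mod$lamp_spectrum, tolerance = 1e-12)
  expect_equal(reference_spectrum(mod, exposure_ms = 60)$intensities,
               2 * 0.99 * mod$lamp_spectrum, tolerance = 1e-12)
  # calibrating a pure-myocardium spectrum leaves the tissue base shape
  cal <- calibrate(mean_normalize(simulate_spectrum("00000000", "R1", mod)),
                   mean_normalize(ref))
  base <- mod$base_spectrum_myocardium / mean(mod$base_spectrum_myocardium)
  expect_equal(cal$intensities, base, tolerance = 1e-9)
})

test_that("subject effects and seeded noise are reproducible", {
  mod <- tiny_model()
  a <- simulate_spectrum("11110000", "R2", mod, rebuild_id = 3L, seed = 99L)
  b <- simulate_spectrum("11110000", "R2", mod, rebuild_id = 3L, seed = 99L)
  expect_identical(a$intensities, b$intensities)
  c <- simulate_spectrum("11110000", "R2", mod, rebuild_id = 4L, seed = 99L)
  expect_false(identical(a$intensities, c$intensities))
  # a local seed must not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123)
  invisible(simulate_spectrum("11110000", "R2", mod, seed = 5L))
  expect_identical(runif(1), r1)
})

test_that("SNR rises with exposure and falls with fiber distance", {
  mod <- tiny_model(64)
  snr_of <- function(fiber, exposure, seed) {
    reps <- lapply(seq_len(60), function(i) {
      simulate_spectrum("00000000", fiber, mod, exposure_ms = exposure,
                        seed = seed + i)
    })
    compute_snr(reps)
  }
  s30 <- snr_of("R5", 30, 1000L)
  s1 <- snr_of("R5", 1, 2000L)
  expect_gt(s30, s1)
  by_fiber <- vapply(paste0("R", 1:5), snr_of, numeric(1),
                     exposure = 30, seed = 3000L)
  expect_true(all(diff(by_fiber) < 0))
})

test_that("study simulation reproduces the protocol counts deterministically", {
  mod <- tiny_model(8)
  vol <- simulate_study(study_design("volume"), mod, seed = 4)
  expect_identical(nrow(vol$manifest), 9L * 3L * 5L * 10L)  # 1350
  perm <- simulate_study(study_design("permuted"), mod, seed = 4)
  expect_identical(nrow(perm$manifest), 900L)
  expect_identical(ncol(perm$spectra), 900L)
  # deterministic given the seed
  vol2 <- simulate_study(study_design("volume"), mod, seed = 4)
  expect_identical(vol$spectra, vol2$spectra)
  expect_identical(vol$manifest, vol2$manifest)
  # every class has n_rebuilds distinct rebuild ids, disjoint across classes
  rb <- split(vol$manifest$rebuild_id, vol$manifest$construct_label)
  expect_true(all(vapply(rb, function(x) length(unique(x)), integer(1)) == 3L))
  expect_identical(length(unique(vol$manifest$rebuild_id)), 9L * 3L)
  broken <- study_design("depth")
  broken$n_rebuilds <- 1L
  expect_error(simulate_study(broken, mod, seed = 1), "2 rebuilds")
})

test_that("noise-free class spectra are pairwise distinct and binary constructs separate", {
  mod0 <- noise_free_model(32)
  classes <- study_design("volume")$classes
  for (f in c("R1", "R5")) {
    shapes <- vapply(classes, function(cl) {
      norm_int(simulate_spectrum(cl, f, mod0))
    }, numeric(32))
    d <- as.matrix(stats::dist(t(shapes)))
    expect_true(all(d[upper.tri(d)] > 1e-6))
  }
  # nearest-centroid on noise-free templates classifies binary spectra
  # perfectly under the default noise model
  mod <- tiny_model(32)
  templates <- vapply(c("00000000", "11111111"), function(cl) {
    norm_int(simulate_spectrum(cl, "R3", mod0))
  }, numeric(32))
  hits <- vapply(1:40, function(i) {
    truth <- c("00000000", "11111111")[1 + i %% 2]
    s <- simulate_spectrum(truth, "R3", mod, rebuild_id = i, seed = 100L + i)
    pred <- colnames(templates)[which.min(colSums((norm_int(s) - templates)^2))]
    pred == truth
  }, logical(1))
  expect_true(all(hits))
})

test_that("proximal fibers resolve shallow insets, distal fibers deep insets", {
  mod <- noise_free_model(64)
  D <- function(f, cl, ref = "11111111") {
    sqrt(sum((norm_int(simulate_spectrum(cl, f, mod)) -
                norm_int(simulate_spectrum(ref, f, mod)))^2))
  }
  # relative sensitivity to the shallow inset grows monotonically with
  # fiber distance: R1 sees "11000000" as nearly pure aorta while R5
  # still sees the myocardium beneath it
  ratios <- vapply(paste0("R", 1:5),
                   function(f) D(f, "11000000") / D(f, "00000011"),
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
  # the deepest inset is essentially invisible to R1 but not to R5
  expect_gt(D("R5", "00000011", ref = "00000000"),
            100 * D("R1", "00000011", ref = "00000000"))
})
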