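# Shared fixtures: tiny grids and models keep the suite fast while
# exercising the same code paths as full-resolution runs.

tiny_grid <- function(n = 16L) default_wavelength_grid(n)

tiny_model <- function(n = 16L, ...) {
  tissue_optical_model(default_wavelength_grid(n), ...)
}

noise_free_model <- function(n = 16L) {
  tissue_optical_model(default_wavelength_grid(n), read_noise_sigma = 0,
                       shot_noise_scale = 0, subject_sigma = 0)
}

flat_spectrum <- function(value, n = 16L, ...) {
  spectrum(tiny_grid(n), rep(value, n), ...)
}

# direct evaluation of the product-moment correlation formula, the
# independent oracle for pearson_correlation()
brute_force_pearson <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) /
    (sqrt(sum((x - xm)^2)) * sqrt(sum((y - ym)^2)))
}

# small study design for fast CNN protocol tests
quick_design <- function(name = "binary", n_rebuilds = 3L, spectra = 4L,
                         fibers = c("R1", "R5")) {
  study_design(name, n_rebuilds = n_rebuilds,
               spectra_per_fiber_per_rebuild = spectra, fibers = fibers)
}

# keeps metadata while replacing intensities
with_intensities_test <- function(s, v) {
  spectrum(s$wavelengths, v, fiber_id = s$meta$fiber_id,
           construct_label = s$meta$construct_label,
           rebuild_id = s$meta$rebuild_id, exposure_ms = s$meta$exposure_ms)
}

quick_cnn_config <- function(input_length, ...) {
  cnn_config(input_length = input_length, max_epochs = 150L,
             patience_epochs = 150L, n_replicates = 2L, ...)
}
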