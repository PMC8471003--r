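#' Probe fiber geometry
#'
#' Geometry of the spectroscopic probe: one 200 um-core illumination fiber
#' surrounded by five 105 um-core collection fibers `R1`..`R5` at
#' center-to-center separations of 210, 345, 480, 615 and 750 um.
#'
#' @return Data frame with columns `fiber_id`, `r_sd_um` (source-detector
#'   separation), `illumination_core_um`, `collection_core_um`.
#' @export
fiber_geometry <- function() {
  data.frame(
    fiber_id = paste0("R", 1:5),
    r_sd_um = c(210, 345, 480, 615, 750),
    illumination_core_um = 200,
    collection_core_um = 105,
    stringsAsFactors = FALSE
  )
}

#' Modal sampling depth of the photon banana path
#'
#' For an illumination and a collection fiber normal to the surface of a
#' turbid medium, the modal line of the detected light distribution
#' follows a banana-shaped profile whose maximal depth is approximately
#' `r_sd / (2 * sqrt(2))`, with `r_sd` the center-to-center fiber
#' separation. Larger separations therefore probe deeper tissue.
#'
#' @param r_sd_um Source-detector separation in um, >= 0 (vectorized).
#' @return Modal depth `z_max` in um.
#' @export
#' @examples
#' round(depth_sensitivity(c(210, 750))) # 74, 265
depth_sensitivity <- function(r_sd_um) {
  if (any(r_sd_um < 0)) stop("r_sd_um must be non-negative", call. = FALSE)
  r_sd_um / (2 * sqrt(2))
}

#' Tissue optical forward model
#'
#' Parameters of the seeded forward simulator that emulates reflectance
#' spectra from the layered constructs. The clean signal for a construct is
#' a depth-weighted mixture of the two tissue base spectra under a lamp
#' envelope; collection amplitude decays with fiber separation; noise has a
#' fixed read component and a shot component growing with the square root
#' of the signal; each rebuild carries a multiplicative gain and a smooth
#' spectral tilt so that hold-out by rebuild is genuinely harder than a
#' random split.
#'
#' Defaults (chosen once as a plausible desk-scale emulation):
#' * base spectra: smooth positive curves with aorta brighter than
#'   myocardium at every wavelength and different shapes (the aorta's
#'   higher collagen/nuclear density raises its scattering);
#' * `sensitivity_decay` 120 um: e-folding of a layer's weight with its
#'   distance from the fiber's modal depth, at the most proximal fiber;
#'   the e-folding grows linearly with the source-detector separation
#'   (`decay_separation_exponent` 1), reflecting that wider separations
#'   sample a broader and deeper banana-shaped volume -- this is what
#'   gives distal fibers depth information that proximal fibers lack;
#' * `amplitude_exponent` 1.5: collected amplitude scales with
#'   `(r_sd(R1)/r_sd)^1.5`, so distal fibers are dimmer and noisier;
#' * `read_noise_sigma` 0.008, `shot_noise_scale` 0.01: tuned so SNR at
#'   the default 30 ms exposure is high for R1 and under ~10 for R5;
#' * `subject_sigma` 0.05: 5% log-normal rebuild gain and tilt scale.
#'
#' @param wavelengths Wavelength grid in nm (default the full 3587-sample
#'   grid; use a shorter [default_wavelength_grid()] for fast studies).
#' @param sensitivity_decay Depth-weight e-folding scale in um at the most
#'   proximal fiber (R1).
#' @param decay_separation_exponent Exponent with which the e-folding
#'   scale grows with `r_sd / r_sd(R1)`; 0 gives one common scale for all
#'   fibers.
#' @param read_noise_sigma Additive Gaussian noise sd (intensity units).
#' @param shot_noise_scale Scale of signal-dependent Gaussian noise.
#' @param subject_sigma Stddev of per-rebuild log-gain and spectral tilt.
#' @param amplitude_exponent Exponent of the fiber-distance attenuation.
#' @param exposure_reference_ms Exposure at which amplitudes are defined
#'   (default 30 ms); signal scales linearly with exposure relative to it.
#' @param subject_seed Integer offset deterministically mapping rebuild ids
#'   to their subject effects.
#' @return An object of class `lss_optical_model`.
#' @export
tissue_optical_model <- function(wavelengths = default_wavelength_grid(),
                                 sensitivity_decay = 120,
                                 decay_separation_exponent = 1,
                                 read_noise_sigma = 0.008,
                                 shot_noise_scale = 0.01,
                                 subject_sigma = 0.05,
                                 amplitude_exponent = 1.5,
                                 exposure_reference_ms = 30,
                                 subject_seed = 0L) {
  stopifnot(sensitivity_decay > 0, read_noise_sigma >= 0,
            shot_noise_scale >= 0, subject_sigma >= 0,
            exposure_reference_ms > 0)
  x <- (wavelengths - 500) / 600  # 0..1 over the default span
  myocardium <- 0.35 + 0.30 * exp(-((wavelengths - 550) / 70)^2) - 0.15 * x
  aorta      <- 0.75 + 0.10 * exp(-((wavelengths - 600) / 150)^2) - 0.05 * x
  # broad tungsten-halogen-like envelope rising into the NIR
  lamp <- 0.25 + 0.75 * exp(-((wavelengths - 900) / 400)^2)
  stopifnot(all(myocardium > 0), all(aorta > myocardium), all(lamp > 0))
  structure(
    list(
      wavelengths = wavelengths,
      base_spectrum_myocardium = myocardium,
      base_spectrum_aorta = aorta,
      lamp_spectrum = lamp,
      sensitivity_decay = sensitivity_decay,
      decay_separation_exponent = decay_separation_exponent,
      read_noise_sigma = read_noise_sigma,
      shot_noise_scale = shot_noise_scale,
      subject_sigma = subject_sigma,
      amplitude_exponent = amplitude_exponent,
      exposure_reference_ms = exposure_reference_ms,
      subject_seed = as.integer(subject_seed),
      layer_thickness_um = 200,
      n_layers = 8L
    ),
    class = "lss_optical_model"
  )
}

#' @rdname tissue_optical_model
#' @param noise_scale Multiplier applied to both noise parameters and the
#'   subject variability; `noise_scale = 0` gives deterministic spectra.
#' @param model Model to rescale.
#' @export
scale_model_noise <- function(model, noise_scale) {
  stopifnot(inherits(model, "lss_optical_model"), noise_scale >= 0)
  model$read_noise_sigma <- model$read_noise_sigma * noise_scale
  model$shot_noise_scale <- model$shot_noise_scale * noise_scale
  model$subject_sigma <- model$subject_sigma * noise_scale
  model
}

# evaluate a closure with a temporary RNG state, restoring the caller's
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# per-rebuild multiplicative gain and smooth spectral tilt, deterministic
# in (model$subject_seed, rebuild_id)
subject_effect <- function(model, rebuild_id) {
  if (is.na(rebuild_id) || model$subject_sigma == 0) {
    return(rep(1, length(model$wavelengths)))
  }
  z <- with_local_seed(model$subject_seed + 1013L * as.integer(rebuild_id),
                       stats::rnorm(3))
  x <- (model$wavelengths - min(model$wavelengths)) /
    diff(range(model$wavelengths)) - 0.5
  gain <- exp(model$subject_sigma * z[1])
  tilt <- 1 + model$subject_sigma * (z[2] * x + z[3] * (x^2 - 1 / 12))
  pmax(gain * tilt, 0.05)
}

#' Depth weights of the eight construct layers for a collection fiber
#'
#' Discretizes the banana-path sampling profile: layer `k` (depth center
#' `(k - 0.5) * 200` um) receives weight proportional to
#' `exp(-|depth_k - z_max(r_sd)| / decay_f)`, normalized to sum to 1,
#' where the per-fiber e-folding scale
#' `decay_f = sensitivity_decay * (r_sd / r_sd(R1))^decay_separation_exponent`
#' widens with the source-detector separation. Distal fibers therefore
#' both center deeper (larger modal depth) and reach deeper (broader
#' kernel) than proximal fibers.
#'
#' @param fiber_id Collection fiber id `R1`..`R5`.
#' @param model A [tissue_optical_model()].
#' @return Numeric vector of 8 strictly positive weights summing to 1.
#' @export
layer_weights <- function(fiber_id, model) {
  stopifnot(inherits(model, "lss_optical_model"))
  geom <- fiber_geometry()
  if (!fiber_id %in% geom$fiber_id) {
    stop("unknown collection fiber: ", fiber_id, call. = FALSE)
  }
  r_sd <- geom$r_sd_um[geom$fiber_id == fiber_id]
  zmax <- depth_sensitivity(r_sd)
  decay <- model$sensitivity_decay *
    (r_sd / geom$r_sd_um[1])^model$decay_separation_exponent
  depths <- (seq_len(model$n_layers) - 0.5) * model$layer_thickness_um
  w <- exp(-abs(depths - zmax) / decay)
  w / sum(w)
}

fiber_attenuation <- function(fiber_id, model) {
  geom <- fiber_geometry()
  r_sd <- geom$r_sd_um[geom$fiber_id == fiber_id]
  (geom$r_sd_um[1] / r_sd)^model$amplitude_exponent
}

add_acquisition_noise <- function(clean, model) {
  n <- length(clean)
  noisy <- clean +
    stats::rnorm(n, sd = model$read_noise_sigma) +
    stats::rnorm(n, sd = 1) * model$shot_noise_scale * sqrt(pmax(clean, 0))
  pmax(noisy, 0)
}

#' Simulate one construct spectrum
#'
#' Forward model: `lamp * sum_k weight_k * base_k`, where `base_k` is the
#' aorta or myocardium base spectrum according to layer `k` of the
#' construct label, multiplied by the rebuild's subject effect, the
#' exposure ratio, and the fiber-distance attenuation; read and shot noise
#' are then added and the result clipped at zero.
#'
#' @param label Construct label.
#' @param fiber_id Collection fiber `R1`..`R5`.
#' @param model A [tissue_optical_model()].
#' @param rebuild_id Integer subject id (drives the subject effect).
#' @param exposure_ms Exposure in ms (default 30).
#' @param seed Optional integer; when given, noise is drawn under a local
#'   RNG seeded with it, leaving the caller's RNG untouched.
#' @return A [spectrum()] carrying the full acquisition metadata.
#' @export
simulate_spectrum <- function(label, fiber_id, model, rebuild_id = 1L,
                              exposure_ms = 30, seed = NULL) {
  assert_construct_label(label)
  stopifnot(inherits(model, "lss_optical_model"), exposure_ms > 0)
  w <- layer_weights(fiber_id, model)
  bits <- label_bits(label)
  mix <- rep(0, length(model$wavelengths))
  for (k in seq_along(bits)) {
    base <- if (bits[k] == 1L) model$base_spectrum_aorta else model$base_spectrum_myocardium
    mix <- mix + w[k] * base
  }
  clean <- model$lamp_spectrum * mix *
    subject_effect(model, rebuild_id) *
    (exposure_ms / model$exposure_reference_ms) *
    fiber_attenuation(fiber_id, model)
  noisy <- if (is.null(seed)) add_acquisition_noise(clean, model) else
    with_local_seed(seed, add_acquisition_noise(clean, model))
  spectrum(model$wavelengths, noisy, fiber_id = fiber_id,
           construct_label = label, rebuild_id = rebuild_id,
           exposure_ms = exposure_ms)
}

#' Simulate a reflectance-standard spectrum
#'
#' The white diffuse reflectance standard reflects 99% of the lamp output;
#' its simulated spectrum is `0.99 * lamp` scaled by the exposure ratio,
#' with the same acquisition noise model as tissue spectra.
#'
#' @inheritParams simulate_spectrum
#' @return A [spectrum()] with `fiber_id = "standard"`.
#' @export
reference_spectrum <- function(model, exposure_ms = 30, seed = NULL) {
  stopifnot(inherits(model, "lss_optical_model"), exposure_ms > 0)
  clean <- 0.99 * model$lamp_spectrum *
    (exposure_ms / model$exposure_reference_ms)
  noisy <- if (is.null(seed)) add_acquisition_noise(clean, model) else
    with_local_seed(seed, add_acquisition_noise(clean, model))
  spectrum(model$wavelengths, noisy, fiber_id = "standard",
           exposure_ms = exposure_ms)
}

#' Simulate a full study dataset
#'
#' Emulates the acquisition protocol: for every class of the design, each
#' of `n_rebuilds` construct rebuilds is "measured"
#' `spectra_per_fiber_per_rebuild` times per collection fiber at the given
#' exposure. Rebuild ids are unique across the dataset (each physical
#' rebuild carries its own subject effect), and the replicate index ties
#' together the spectra of the five fibers acquired at one probe
#' placement, which is what two-fiber concatenation pairs on.
#'
#' @param design A [study_design()].
#' @param model A [tissue_optical_model()].
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param exposure_ms Exposure in ms (default 30).
#' @return An object of class `lss_dataset`: list with `wavelengths`,
#'   `spectra` (matrix, one column per spectrum), and `manifest`
#'   (data.frame: `spectrum_id`, `construct_label`, `fiber_id`,
#'   `rebuild_id`, `rep_index`, `exposure_ms`, `role`).
#' @export
#' @examples
#' d <- simulate_study(study_design("binary"),
#'                     tissue_optical_model(default_wavelength_grid(64)),
#'                     seed = 1)
#' nrow(d$manifest) # 2 * 3 * 5 * 10
simulate_study <- function(design, model, seed, exposure_ms = 30) {
  stopifnot(inherits(design, "lss_study_design"),
            inherits(model, "lss_optical_model"))
  if (design$n_rebuilds < 2L) {
    stop("subject-wise hold-out requires at least 2 rebuilds per class",
         call. = FALSE)
  }
  n <- length(design$classes) * design$n_rebuilds * length(design$fibers) *
    design$spectra_per_fiber_per_rebuild
  spectra <- matrix(NA_real_, nrow = length(model$wavelengths), ncol = n)
  manifest <- data.frame(
    spectrum_id = sprintf("s%05d", seq_len(n)),
    construct_label = character(n),
    fiber_id = character(n),
    rebuild_id = integer(n),
    rep_index = integer(n),
    exposure_ms = rep(exposure_ms, n),
    role = rep("tissue", n),
    stringsAsFactors = FALSE
  )
  with_local_seed(seed, {
    col <- 0L
    rebuild_counter <- 0L
    for (cls in design$classes) {
      for (rb in seq_len(design$n_rebuilds)) {
        rebuild_counter <- rebuild_counter + 1L
        for (rep_i in seq_len(design$spectra_per_fiber_per_rebuild)) {
          for (fib in design$fibers) {
            col <- col + 1L
            s <- simulate_spectrum(cls, fib, model,
                                   rebuild_id = rebuild_counter,
                                   exposure_ms = exposure_ms)
            spectra[, col] <- s$intensities
            manifest$construct_label[col] <- cls
            manifest$fiber_id[col] <- fib
            manifest$rebuild_id[col] <- rebuild_counter
            manifest$rep_index[col] <- rep_i
          }
        }
      }
    }
  })
  structure(
    list(wavelengths = model$wavelengths, spectra = spectra,
         manifest = manifest, design_name = design$name),
    class = "lss_dataset"
  )
}

#' @export
print.lss_dataset <- function(x, ...) {
  cat(sprintf(
    "<lss_dataset> %d spectra x %d wavelengths (%.0f-%.0f nm), %d classes, %d rebuilds\n",
    ncol(x$spectra), nrow(x$spectra), min(x$wavelengths), max(x$wavelengths),
    length(unique(x$manifest$construct_label)),
    length(unique(x$manifest$rebuild_id))
  ))
  invisible(x)
}
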