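#' Default wavelength grid
#'
#' Uniform wavelength grid of the CCD spectrometer emulated throughout the
#' package: `n` samples spanning 500--1100 nm. The full-resolution grid has
#' 3587 samples (spacing ~0.167 nm); reduced grids with the same span are
#' used for fast simulation studies.
#'
#' @param n Number of samples (default 3587).
#' @param range Wavelength span in nm (default `c(500, 1100)`).
#' @return Numeric vector of strictly increasing wavelengths in nm.
#' @export
#' @examples
#' g <- default_wavelength_grid(128)
#' range(g)
default_wavelength_grid <- function(n = 3587L, range = c(500, 1100)) {
  stopifnot(n >= 2, length(range) == 2, range[2] > range[1])
  seq(range[1], range[2], length.out = n)
}

#' Construct a Spectrum object
#'
#' A `Spectrum` couples one reflectance trace on a fixed wavelength grid
#' with its acquisition metadata: collection fiber (`R1`--`R5`, or
#' `"standard"` for the white diffuse reflectance standard), the construct
#' label of the measured tissue stack, the rebuild (subject) id, and the
#' exposure time in milliseconds.
#'
#' @param wavelengths Strictly increasing numeric vector (nm), length >= 2.
#' @param intensities Non-negative finite numeric vector, same length.
#' @param fiber_id One of `"R1"`..`"R5"` or `"standard"`.
#' @param construct_label Optional 8-character binary construct label.
#' @param rebuild_id Optional integer subject id.
#' @param exposure_ms Positive exposure time in ms (default 30).
#' @return An object of class `lss_spectrum`.
#' @export
#' @examples
#' s <- spectrum(default_wavelength_grid(16), rep(1, 16), fiber_id = "R1")
spectrum <- function(wavelengths, intensities, fiber_id = "standard",
                     construct_label = NULL, rebuild_id = NA_integer_,
                     exposure_ms = 30) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least 2 samples", call. = FALSE)
  }
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  }
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!fiber_id %in% c(paste0("R", 1:5), "standard")) {
    stop("fiber_id must be one of R1..R5 or 'standard'", call. = FALSE)
  }
  if (!is.null(construct_label)) assert_construct_label(construct_label)
  if (!is.na(exposure_ms) && exposure_ms <= 0) {
    stop("exposure_ms must be positive", call. = FALSE)
  }
  structure(
    list(
      wavelengths = wavelengths,
      intensities = intensities,
      meta = list(
        fiber_id = fiber_id,
        construct_label = construct_label,
        rebuild_id = as.integer(rebuild_id),
        exposure_ms = exposure_ms
      )
    ),
    class = "lss_spectrum"
  )
}

#' @export
print.lss_spectrum <- function(x, ...) {
  lab <- if (is.null(x$meta$construct_label)) "<none>" else x$meta$construct_label
  cat(sprintf(
    "<lss_spectrum> %d samples, %.1f-%.1f nm | fiber %s | construct %s | rebuild %s | %g ms\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$meta$fiber_id, lab,
    ifelse(is.na(x$meta$rebuild_id), "<none>", x$meta$rebuild_id),
    x$meta$exposure_ms
  ))
  invisible(x)
}

#' @export
length.lss_spectrum <- function(x) length(x$wavelengths)

is_spectrum <- function(x) inherits(x, "lss_spectrum")

# identical grid check used by binary spectrum operations
assert_same_grid <- function(a, b) {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(a$wavelengths != b$wavelengths)) {
    stop("spectra are not on the identical wavelength grid", call. = FALSE)
  }
  invisible(TRUE)
}

# replace intensities, keeping grid and metadata
with_intensities <- function(s, intensities) {
  s$intensities <- as.numeric(intensities)
  s
}
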