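#' Normalize a spectrum to its mean intensity
#'
#' Divides the intensities by their mean so that the normalized spectrum has
#' mean intensity exactly 1. Normalization removes the absolute intensity
#' scale (light source power, fiber coupling, exposure) and keeps only
#' spectral shape, which is what the classifier consumes.
#'
#' @param s A [spectrum()].
#' @return A `lss_spectrum` with mean intensity 1; metadata preserved.
#' @export
#' @examples
#' s <- spectrum(default_wavelength_grid(4), c(2, 2, 2, 2))
#' mean_normalize(s)$intensities
mean_normalize <- function(s) {
  stopifnot(is_spectrum(s))
  m <- mean(s$intensities)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate spectrum: mean intensity must be positive", call. = FALSE)
  }
  with_intensities(s, s$intensities / m)
}

is_mean_normalized <- function(s, tol = 1e-6) {
  abs(mean(s$intensities) - 1) <= tol
}

#' Calibrate a spectrum against a reflectance-standard spectrum
#'
#' Divides a tissue spectrum pointwise by a spectrum measured from a white
#' diffuse reflectance standard, removing the lamp/instrument spectral
#' envelope, then re-normalizes to mean 1. Both inputs are expected to be
#' mean-normalized; because the pointwise ratio is followed by mean
#' re-normalization, any residual common scale cancels.
#'
#' @param s Tissue [spectrum()].
#' @param reference Reflectance-standard [spectrum()], strictly positive,
#'   on the identical wavelength grid.
#' @return Calibrated, mean-normalized `lss_spectrum` (metadata of `s`).
#' @export
calibrate <- function(s, reference) {
  stopifnot(is_spectrum(s), is_spectrum(reference))
  assert_same_grid(s, reference)
  if (any(reference$intensities <= 0)) {
    stop("reference spectrum must be strictly positive at all wavelengths",
         call. = FALSE)
  }
  mean_normalize(with_intensities(s, s$intensities / reference$intensities))
}

#' Pearson correlation between two spectra
#'
#' The product-moment correlation of two intensity traces on a common
#' wavelength grid, used to compare spectra across tissues, fixation
#' states, or probe orientations.
#'
#' @param x,y Spectra on the identical grid with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is_spectrum(x), is_spectrum(y))
  assert_same_grid(x, y)
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::var(x$intensities) == 0 || stats::var(y$intensities) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  stats::cor(x$intensities, y$intensities)
}

#' Signal-to-noise ratio of replicate spectra
#'
#' SNR of a set of replicate acquisitions of the same target, fiber, and
#' exposure: the per-wavelength ratio of the replicate mean to the
#' replicate standard deviation, averaged over the wavelength band. The
#' statistic is invariant to a common rescaling of all replicates.
#'
#' @param replicates List of >= 2 spectra on the identical grid.
#' @param band Optional `c(lo, hi)` wavelength window (nm) over which the
#'   per-wavelength ratios are averaged; default is the full grid.
#' @return Positive SNR value. If the replicates are identical everywhere
#'   (zero noise) the sentinel `Inf` is returned with a warning.
#' @export
compute_snr <- function(replicates, band = NULL) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  lapply(replicates, function(s) stopifnot(is_spectrum(s)))
  for (s in replicates[-1]) assert_same_grid(replicates[[1]], s)
  wl <- replicates[[1]]$wavelengths
  mat <- do.call(rbind, lapply(replicates, `[[`, "intensities"))
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, stats::sd)
  keep <- rep(TRUE, length(wl))
  if (!is.null(band)) {
    stopifnot(length(band) == 2, band[2] > band[1])
    keep <- wl >= band[1] & wl <= band[2]
    if (!any(keep)) stop("band contains no grid samples", call. = FALSE)
  }
  mu <- mu[keep]; sdv <- sdv[keep]
  if (all(sdv == 0)) {
    warning("replicates are identical: SNR is infinite")
    return(Inf)
  }
  ok <- sdv > 0
  mean(mu[ok] / sdv[ok])
}

# Gaussian smoothing with kernel stddev given in samples; same-length
# output, edges handled by renormalizing the truncated kernel.
gaussian_smooth <- function(x, stddev_samples) {
  stopifnot(stddev_samples >= 0)
  if (stddev_samples == 0) return(x)
  r <- ceiling(4 * stddev_samples)
  k <- stats::dnorm(-r:r, sd = stddev_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, r), x, rep(0, r))
  mp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(xp, k, sides = 2)[(r + 1):(r + n)]
  den <- stats::filter(mp, k, sides = 2)[(r + 1):(r + n)]
  as.numeric(num / den)
}

#' Smoothed difference curves between a construct group and a reference group
#'
#' For visualizing where on the wavelength axis a construct's spectra
#' depart from a reference construct (typically the all-aorta stack):
#' subtracts the mean reference spectrum from every group spectrum, then
#' reports the per-wavelength mean and standard deviation of those
#' differences, each smoothed with a 1D Gaussian kernel. The default
#' kernel stddev of 20 samples corresponds to ~3.3 nm on the
#' full-resolution 3587-sample grid.
#'
#' @param group List of normalized spectra of the construct of interest.
#' @param reference_group List of normalized reference spectra (same grid).
#' @param kernel_stddev_samples Gaussian kernel stddev in grid samples
#'   (default 20).
#' @return List with `wavelengths`, `mean` and `sd` curves (grid length).
#' @export
smoothed_difference <- function(group, reference_group,
                                kernel_stddev_samples = 20) {
  if (length(group) == 0L || length(reference_group) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  lapply(c(group, reference_group), function(s) stopifnot(is_spectrum(s)))
  for (s in c(group, reference_group)[-1]) {
    assert_same_grid(group[[1]], s)
  }
  ref_mean <- colMeans(do.call(rbind, lapply(reference_group, `[[`, "intensities")))
  diffs <- do.call(rbind, lapply(group, function(s) s$intensities - ref_mean))
  mcurve <- colMeans(diffs)
  scurve <- if (nrow(diffs) > 1L) apply(diffs, 2, stats::sd) else rep(0, ncol(diffs))
  list(
    wavelengths = group[[1]]$wavelengths,
    mean = gaussian_smooth(mcurve, kernel_stddev_samples),
    sd = gaussian_smooth(scurve, kernel_stddev_samples)
  )
}

#' Concatenate two single-fiber spectra into a combined feature vector
#'
#' Combined two-fiber features are formed by appending the intensity trace
#' of the higher-index collection fiber to that of the lower-index fiber.
#' On the full-resolution 3587-sample grid the combined vector has length
#' 7174. Both spectra must come from the same construct and rebuild and
#' must already be mean-normalized.
#'
#' @param s1,s2 Normalized spectra from two distinct collection fibers of
#'   the same construct and rebuild, identical grid.
#' @return An object of class `lss_features`: list with `values`,
#'   `source_fibers` (ordered ascending by fiber index), `label`,
#'   `rebuild_id`.
#' @export
concatenate_fiber_spectra <- function(s1, s2) {
  stopifnot(is_spectrum(s1), is_spectrum(s2))
  assert_same_grid(s1, s2)
  f1 <- s1$meta$fiber_id; f2 <- s2$meta$fiber_id
  if (!all(c(f1, f2) %in% paste0("R", 1:5))) {
    stop("both spectra must come from collection fibers R1..R5", call. = FALSE)
  }
  if (f1 == f2) stop("cannot combine a fiber with itself", call. = FALSE)
  if (!identical(s1$meta$construct_label, s2$meta$construct_label)) {
    stop("construct labels differ between the two fibers", call. = FALSE)
  }
  if (!identical(s1$meta$rebuild_id, s2$meta$rebuild_id)) {
    stop("rebuild ids differ between the two fibers", call. = FALSE)
  }
  if (!is_mean_normalized(s1) || !is_mean_normalized(s2)) {
    stop("spectra must be mean-normalized before concatenation", call. = FALSE)
  }
  if (fiber_index(f1) > fiber_index(f2)) {
    tmp <- s1; s1 <- s2; s2 <- tmp
    f1 <- s1$meta$fiber_id; f2 <- s2$meta$fiber_id
  }
  structure(
    list(
      values = c(s1$intensities, s2$intensities),
      source_fibers = c(f1, f2),
      label = s1$meta$construct_label,
      rebuild_id = s1$meta$rebuild_id
    ),
    class = "lss_features"
  )
}

fiber_index <- function(fiber_id) as.integer(sub("^R", "", fiber_id))
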