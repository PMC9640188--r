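#' Optical and photometric parameters of a simulated acquisition
#'
#' Bundles the calibration and noise parameters used by the forward model:
#' pixel pitch, z step, anisotropic PSF widths, background, brightness per
#' microtubule, detector statistics, and the axial scaling factor that converts
#' stage z-steps into true sample-depth distances under refractive-index
#' mismatch with an oil objective (default 0.81).
#'
#' Two presets are provided. \code{"confocal"} uses an 83 nm pixel and a
#' 0.5 um z step; \code{"sted"} uses a 20 nm pixel and a 0.3 um z step.
#' PSF widths are typical values for the two modalities (they are acquisition
#' properties, not measured here): sigma_xy 0.11 um (confocal) / 0.035 um
#' (STED), sigma_z 0.35 um for both.
#'
#' @param modality "confocal" or "sted"; selects the preset defaults.
#' @param pixel_size_xy in-plane pixel size, um/pixel.
#' @param z_step stage distance between acquired planes, um.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations, um.
#'   \code{psf_sigma_z} is expressed in stage-z um.
#' @param background_level additive background, a.u. per voxel.
#' @param unit_brightness line brightness of a single microtubule,
#'   a.u. per um of fiber length.
#' @param poisson_gain photons per a.u.; shot noise is Poisson at this gain.
#' @param read_noise_sigma additive Gaussian read noise, a.u.
#' @param axial_scale true-z per stage-z (dimensionless, in (0, 1]).
#' @param frame_interval_s time between frames for time-lapse rendering, s.
#' @return An object of class \code{"optics_params"}.
#' @examples
#' op <- optics_params("sted")
#' op$pixel_size_xy
#' @export
optics_params <- function(modality = c("confocal", "sted"),
                          pixel_size_xy = NULL,
                          z_step = NULL,
                          psf_sigma_xy = NULL,
                          psf_sigma_z = 0.35,
                          background_level = NULL,
                          unit_brightness = 2000,
                          poisson_gain = 1,
                          read_noise_sigma = 1,
                          axial_scale = 0.81,
                          frame_interval_s = 10) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    confocal = list(pixel_size_xy = 0.083, z_step = 0.5,
                    psf_sigma_xy = 0.11, background_level = 10),
    sted     = list(pixel_size_xy = 0.020, z_step = 0.3,
                    psf_sigma_xy = 0.035, background_level = 5))
  if (is.null(pixel_size_xy)) pixel_size_xy <- defaults$pixel_size_xy
  if (is.null(z_step)) z_step <- defaults$z_step
  if (is.null(psf_sigma_xy)) psf_sigma_xy <- defaults$psf_sigma_xy
  if (is.null(background_level)) background_level <- defaults$background_level

  stopifnot(pixel_size_xy > 0, z_step > 0, psf_sigma_xy > 0, psf_sigma_z > 0)
  if (!(axial_scale > 0 && axial_scale <= 1))
    stop("axial_scale must lie in (0, 1]")
  if (background_level < 0) stop("background_level must be >= 0")
  if (unit_brightness <= 0) stop("unit_brightness must be > 0")
  if (poisson_gain <= 0) stop("poisson_gain must be > 0")
  if (read_noise_sigma < 0) stop("read_noise_sigma must be >= 0")

  structure(list(
    modality = modality,
    pixel_size_xy = pixel_size_xy,
    z_step = z_step,
    psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z,
    background_level = background_level,
    unit_brightness = unit_brightness,
    poisson_gain = poisson_gain,
    read_noise_sigma = read_noise_sigma,
    axial_scale = axial_scale,
    frame_interval_s = frame_interval_s
  ), class = "optics_params")
}

#' @export
print.optics_params <- function(x, ...) {
  cat(sprintf(
    "optics_params [%s]: pixel %.3f um, z step %.2f um, PSF sigma (%.3f, %.2f) um\n",
    x$modality, x$pixel_size_xy, x$z_step, x$psf_sigma_xy, x$psf_sigma_z))
  cat(sprintf(
    "  background %.1f a.u., %.0f a.u./MT/um, gain %.1f ph/a.u., read noise %.1f, axial scale %.2f\n",
    x$background_level, x$unit_brightness, x$poisson_gain,
    x$read_noise_sigma, x$axial_scale))
  invisible(x)
}

# true z distance represented by one plane step
plane_pitch_um <- function(optics) optics$z_step * optics$axial_scale
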