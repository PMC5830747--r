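#' Camera model
#'
#' A simple trichromatic camera: three Gaussian channel sensitivities, a
#' power-law (gamma) tone curve and additive read noise on the digital
#' numbers. Channel peaks default to 600/540/460 nm — deliberately different
#' from any avian receptor, so that mapping calibrated camera channels onto
#' cone catches is a genuine regression problem rather than an identity.
#'
#' @param sensitivities list of three sensitivity [spectral_curve()]s
#'   (R, G, B order).
#' @param gamma tone-curve exponent (> 0); digital numbers follow
#'   `gain * catch^(1/gamma)`.
#' @param gain multiplicative gain (> 0); with the default 8-bit depth a gain
#'   of 255 maps a perfect white reflector to full scale.
#' @param noise_sd additive Gaussian noise standard deviation in digital
#'   numbers (>= 0).
#' @param bit_depth integer bit depth of the sensor output.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(sensitivities = default_camera_sensitivities(),
                         gamma = 2.2, gain = 255, noise_sd = 2,
                         bit_depth = 8L) {
  stopifnot(is.list(sensitivities), length(sensitivities) == 3L)
  for (s in sensitivities) {
    stopifnot(inherits(s, "spectral_curve"))
    if (any(s$values < 0)) stop("camera sensitivities must be >= 0")
  }
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  if (!is.numeric(gain) || gain <= 0) stop("'gain' must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(sensitivities = sensitivities, gamma = gamma, gain = gain,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 dn_max = 2^as.integer(bit_depth) - 1),
            class = "camera_model")
}

#' @rdname camera_model
#' @param wavelengths wavelength grid.
#' @export
default_camera_sensitivities <- function(wavelengths = default_wavelengths()) {
  peaks <- c(600, 540, 460)
  lapply(peaks, function(p) {
    spectral_curve(wavelengths,
                   exp(-((wavelengths - p)^2) / (2 * 35^2)),
                   kind = "sensitivity")
  })
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model: gamma %.3g, gain %.4g, noise sd %.3g DN, %d-bit>\n",
    x$gamma, x$gain, x$noise_sd, x$bit_depth))
  invisible(x)
}

#' Camera channel catches of a reflectance spectrum
#'
#' Reflectance-referenced channel responses: each channel integrates
#' reflectance x illuminant x sensitivity, normalized by illuminant x
#' sensitivity, so a perfect white gives 1.0 in every channel.
#'
#' @param reflectance a reflectance [spectral_curve()].
#' @param camera a [camera_model()].
#' @param illuminant an illuminant [spectral_curve()].
#' @return numeric vector of three channel catches in `[0, 1]`.
#' @export
camera_catch <- function(reflectance, camera,
                         illuminant = illuminant_spectrum("flat")) {
  vapply(camera$sensitivities, function(s) {
    cone_catch(reflectance, illuminant, s)
  }, numeric(1))
}

#' Forward camera tone curve
#'
#' Maps linear channel catches to digital numbers:
#' `DN = gain * catch^(1/gamma)` (+ optional noise), then rounded and clipped
#' to the sensor range when `quantize = TRUE`. The unquantized form is the
#' exact mathematical inverse of [linearize()] and is used by the
#' calibration oracles.
#'
#' @param catch numeric array of linear catches (>= 0).
#' @param camera a [camera_model()].
#' @param quantize round and clip to integer digital numbers?
#' @param noise_sd noise to add in DN; defaults to the camera's.
#' @return numeric array of digital numbers, same shape as `catch`.
#' @export
camera_response <- function(catch, camera, quantize = TRUE,
                            noise_sd = camera$noise_sd) {
  if (any(catch < 0, na.rm = TRUE)) stop("catches must be >= 0")
  dn <- camera$gain * catch^(1 / camera$gamma)
  if (noise_sd > 0) dn <- dn + stats::rnorm(length(dn), 0, noise_sd)
  if (quantize) dn <- pmin(pmax(round(dn), 0), camera$dn_max)
  array(dn, dim = if (is.null(dim(catch))) length(catch) else dim(catch))
}
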