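#' Spectral curves
#'
#' A `spectral_curve` holds non-negative values (reflectance, sensitivity or
#' irradiance) on a strictly increasing wavelength grid in nanometres. All
#' spectral quantities in the package live on a common default grid of
#' 300--700 nm at 1 nm steps, wide enough to cover a UV-sensitive
#' tetrachromat's receptors; integrals are trapezoidal.
#'
#' @param wavelengths numeric vector of wavelengths (nm), strictly increasing.
#' @param values numeric vector of the same length, all values >= 0.
#' @param kind one of `"reflectance"`, `"sensitivity"`, `"illuminant"`.
#'   Reflectances must additionally lie in `[0, 1]`.
#' @return An object of class `spectral_curve`: a list with elements
#'   `wavelengths`, `values` and `kind`.
#' @export
spectral_curve <- function(wavelengths, values, kind = "reflectance") {
  kind <- match.arg(kind, c("reflectance", "sensitivity", "illuminant"))
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("'wavelengths' and 'values' must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectral curve needs at least two grid points", call. = FALSE)
  }
  if (any(!is.finite(wavelengths)) || any(!is.finite(values))) {
    stop("spectral curves must be finite", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("spectral values must be non-negative", call. = FALSE)
  }
  if (kind == "reflectance" && any(values > 1 + 1e-12)) {
    stop("reflectance values must not exceed 1", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectral_curve")
}

#' Default wavelength grid (300--700 nm, 1 nm step)
#' @return numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() seq(300, 700, by = 1)

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve: %s, %d points, %g-%g nm, range [%.4g, %.4g]>\n",
              x$kind, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), min(x$values), max(x$values)))
  invisible(x)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

stopifnot_same_grid <- function(...) {
  curves <- list(...)
  w <- curves[[1]]$wavelengths
  for (cu in curves[-1]) {
    if (length(cu$wavelengths) != length(w) || any(cu$wavelengths != w)) {
      stop("spectral curves are not on a common wavelength grid", call. = FALSE)
    }
  }
  invisible(w)
}

#' Construct parametric reflectance spectra
#'
#' Parametric stand-ins for the reflectances found in a scene of an
#' orange-and-black striped caterpillar on a green stem: a spectrally flat
#' grey, a long-pass sigmoid (the classic shape of orange/red integumental
#' pigments), and a Gaussian peak (green foliage).
#'
#' @param kind `"flat"`, `"longpass_sigmoid"` or `"gaussian_peak"`.
#' @param r constant reflectance for `kind = "flat"` (in `[0, 1]`).
#' @param lambda0 inflection wavelength (nm) of the sigmoid, in `[300, 700]`.
#' @param rmin,rmax lower/upper reflectance asymptotes, `0 <= rmin <= rmax <= 1`.
#' @param width sigmoid steepness (nm) or Gaussian standard deviation (nm), > 0.
#' @param peak peak wavelength (nm) of the Gaussian, in `[300, 700]`.
#' @param wavelengths wavelength grid; defaults to [default_wavelengths()].
#' @return A reflectance [spectral_curve()].
#' @examples
#' grey <- make_spectrum("flat", r = 0.15)
#' orange <- make_spectrum("longpass_sigmoid", lambda0 = 580,
#'                         rmin = 0.05, rmax = 0.60)
#' stem <- make_spectrum("gaussian_peak", peak = 550, width = 40, rmax = 0.35)
#' @export
make_spectrum <- function(kind = c("flat", "longpass_sigmoid", "gaussian_peak"),
                          r = 0.15, lambda0 = 580, rmin = 0.05, rmax = 0.60,
                          width = 20, peak = 550,
                          wavelengths = default_wavelengths()) {
  kind <- match.arg(kind)
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a single value in [0, 1]", nm), call. = FALSE)
    }
  }
  chkrange <- function(v, nm, lo, hi) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo || v > hi) {
      stop(sprintf("'%s' must be a single value in [%g, %g]", nm, lo, hi),
           call. = FALSE)
    }
  }
  vals <- switch(kind,
    flat = {
      chk01(r, "r")
      rep(r, length(wavelengths))
    },
    longpass_sigmoid = {
      chkrange(lambda0, "lambda0", 300, 700)
      chk01(rmin, "rmin"); chk01(rmax, "rmax")
      if (rmin > rmax) stop("'rmin' must not exceed 'rmax'", call. = FALSE)
      if (width <= 0) stop("'width' must be positive", call. = FALSE)
      rmin + (rmax - rmin) / (1 + exp(-(wavelengths - lambda0) / width))
    },
    gaussian_peak = {
      chkrange(peak, "peak", 300, 700)
      chk01(rmax, "rmax")
      if (width <= 0) stop("'width' must be positive", call. = FALSE)
      rmax * exp(-((wavelengths - peak)^2) / (2 * width^2))
    })
  spectral_curve(wavelengths, vals, kind = "reflectance")
}

#' Built-in scene reflectances
#'
#' The default spectra used by the synthetic-scene generator: a long-pass
#' orange (stripe colour), a dark flat black (stripe colour), a green stem
#' peak, and the 15% flat grey calibration standard.
#'
#' @param id one of `"orange"`, `"black"`, `"green_stem"`, `"grey15"`.
#' @param wavelengths wavelength grid.
#' @return A reflectance [spectral_curve()].
#' @export
scene_spectrum <- function(id = c("orange", "black", "green_stem", "grey15"),
                           wavelengths = default_wavelengths()) {
  id <- match.arg(id)
  switch(id,
    orange = make_spectrum("longpass_sigmoid", lambda0 = 580, rmin = 0.05,
                           rmax = 0.60, width = 20, wavelengths = wavelengths),
    black = make_spectrum("flat", r = 0.05, wavelengths = wavelengths),
    green_stem = make_spectrum("gaussian_peak", peak = 550, width = 40,
                               rmax = 0.35, wavelengths = wavelengths),
    grey15 = make_spectrum("flat", r = 0.15, wavelengths = wavelengths))
}

#' Illuminant spectra
#'
#' Catches are reflectance-referenced (the illuminant appears in both
#' numerator and denominator), so the flat equal-energy default cancels for
#' flat reflectances; a smooth daylight-like alternative is provided for
#' sensitivity analyses.
#'
#' @param id `"flat"` (equal-energy) or `"daylight"` (smooth D65-like curve).
#' @param wavelengths wavelength grid.
#' @return An illuminant [spectral_curve()].
#' @export
illuminant_spectrum <- function(id = c("flat", "daylight"),
                                wavelengths = default_wavelengths()) {
  id <- match.arg(id)
  vals <- switch(id,
    flat = rep(1, length(wavelengths)),
    # smooth daylight stand-in: broad hump peaking in the blue-green with a
    # soft UV shoulder
    daylight = 0.6 + 0.4 * exp(-((wavelengths - 480)^2) / (2 * 120^2)))
  spectral_curve(wavelengths, vals, kind = "illuminant")
}

#' Smooth random reflectance spectra
#'
#' Sums of 2--4 broad Gaussians with random centres, widths and amplitudes,
#' rescaled into `[0.02, 0.95]`. These emulate the smooth reflectances of
#' natural objects and are used as training material for the camera-to-cone
#' regression.
#'
#' @param n number of spectra.
#' @param seed RNG seed.
#' @param wavelengths wavelength grid.
#' @return A list of `n` reflectance [spectral_curve()] objects.
#' @export
random_smooth_spectra <- function(n, seed = 1L,
                                  wavelengths = default_wavelengths()) {
  withr::local_seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1L)
    centres <- runif(k, 300, 700)
    widths <- runif(k, 40, 150)
    amps <- runif(k, 0.2, 1)
    v <- rep(0, length(wavelengths))
    for (j in seq_len(k)) {
      v <- v + amps[j] * exp(-((wavelengths - centres[j])^2) / (2 * widths[j]^2))
    }
    lo <- runif(1, 0.02, 0.1)
    hi <- runif(1, 0.4, 0.95)
    rng <- range(v)
    v <- lo + (hi - lo) * (v - rng[1]) / max(rng[2] - rng[1], 1e-12)
    spectral_curve(wavelengths, v, kind = "reflectance")
  })
}

#' Training spectra spanning the scene gamut
#'
#' The camera-to-cone regression is only identifiable on the gamut it is
#' calibrated for: three camera channels underdetermine four receptor
#' catches for arbitrary reflectances, so the training family must span --
#' and stay within -- the spectra the map will be applied to. This draws
#' half flat greys across the reflectance range (the calibration patches
#' live here) and half random convex mixtures of the scene's stripe and
#' stem spectra at varying overall intensity. For generic smooth natural
#' spectra use [random_smooth_spectra()] instead, and expect larger
#' residuals at spectrally extreme points.
#'
#' @param n total number of spectra (>= 3).
#' @param seed RNG seed.
#' @param wavelengths wavelength grid.
#' @return A list of `n` reflectance [spectral_curve()] objects.
#' @export
scene_training_spectra <- function(n = 200, seed = 1L,
                                   wavelengths = default_wavelengths()) {
  n_flat <- floor(n / 2)
  n_mix <- n - n_flat
  base <- lapply(c("orange", "black", "green_stem"), scene_spectrum,
                 wavelengths = wavelengths)
  withr::local_seed(seed)
  flats <- lapply(seq_len(n_flat), function(i) {
    make_spectrum("flat", r = runif(1, 0.02, 0.95), wavelengths = wavelengths)
  })
  mixes <- lapply(seq_len(n_mix), function(i) {
    a <- runif(3)
    a <- a / sum(a)
    v <- a[1] * base[[1]]$values + a[2] * base[[2]]$values +
      a[3] * base[[3]]$values
    v <- pmin(v * runif(1, 0.5, 1.6), 1)
    spectral_curve(wavelengths, v, kind = "reflectance")
  })
  c(flats, mixes)
}

#' Read/write two-column wavelength-value tables
#'
#' Receptor sets, illuminants and reflectances interchange as plain
#' whitespace-separated text with columns `wavelength_nm` and `value`.
#'
#' @param curve a [spectral_curve()].
#' @param path file path.
#' @param kind curve kind used when reading.
#' @return `read_spectrum()` returns a [spectral_curve()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(curve, path) {
  stopifnot(inherits(curve, "spectral_curve"))
  utils::write.table(
    data.frame(wavelength_nm = curve$wavelengths, value = curve$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, kind = "reflectance") {
  tab <- utils::read.table(path, header = TRUE)
  spectral_curve(tab$wavelength_nm, tab$value, kind = kind)
}
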