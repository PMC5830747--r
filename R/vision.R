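#' Avian photoreceptors
#'
#' A receptor couples a visual-pigment template (peak absorbance
#' `lambda_max`), an optional long-pass oil-droplet filter (cut-off
#' `lambda_cut`) and an ocular-media transmission curve. The default set is
#' the starling-like UV-sensitive tetrachromat used throughout: single cones
#' LWS (563 nm), MWS (504 nm), SWS (449 nm), UVS (362 nm) and the double
#' cone D (563 nm, no oil droplet) as the luminance receptor.
#'
#' @param name receptor name.
#' @param lambda_max pigment peak absorbance (nm).
#' @param lambda_cut oil-droplet long-pass cut-off (nm), or `NA` for none.
#' @param media ocular-media transmission [spectral_curve()], or `NULL` for
#'   unity transmission.
#' @return An object of class `receptor`.
#' @export
receptor <- function(name, lambda_max, lambda_cut = NA_real_, media = NULL) {
  if (!is.na(lambda_cut) && lambda_cut < 300) {
    stop("'lambda_cut' must be >= 300 nm when present")
  }
  structure(list(name = name, lambda_max = lambda_max,
                 lambda_cut = lambda_cut, media = media),
            class = "receptor")
}

#' @rdname receptor
#' @param media ocular-media transmission applied to all members of the set.
#' @export
starling_receptors <- function(media = ocular_media()) {
  list(
    LWS = receptor("LWS", 563, 570, media),
    MWS = receptor("MWS", 504, 505, media),
    SWS = receptor("SWS", 449, 445, media),
    UVS = receptor("UVS", 362, NA_real_, media),
    D   = receptor("D", 563, NA_real_, media)
  )
}

#' Ocular media transmission
#'
#' Smooth long-pass transmission of the cornea and lens, half-height near
#' 323 nm — short-wavelength limited but fully transmissive over the
#' UVS pigment peak.
#'
#' @param lambda_half half-transmission wavelength (nm).
#' @param slope transition width (nm).
#' @param wavelengths wavelength grid.
#' @return A sensitivity [spectral_curve()] with values in `[0, 1]`.
#' @export
ocular_media <- function(lambda_half = 323, slope = 8,
                         wavelengths = default_wavelengths()) {
  spectral_curve(wavelengths,
                 1 / (1 + exp(-(wavelengths - lambda_half) / slope)),
                 kind = "sensitivity")
}

# Govardovskii-style vitamin-A1 alpha-band pigment template; returns
# absorbance normalized to 1 at lambda_max.
a1_template <- function(wavelengths, lambda_max) {
  x <- lambda_max / wavelengths
  a <- 0.8795 + 0.0459 * exp(-((lambda_max - 300)^2) / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

#' Receptor spectral sensitivity
#'
#' Evaluates the pigment template at the receptor's `lambda_max`
#' (normalized to a maximum of 1), then multiplies by the oil-droplet
#' long-pass transmission (when present) and the ocular-media transmission.
#'
#' @param rec a [receptor()].
#' @param wavelengths wavelength grid covering `[300, 700]` nm.
#' @param template `"a1"` for the vitamin-A1 nomogram (default) or
#'   `"gaussian"` for a simple Gaussian fallback (sd 60 nm).
#' @param droplet_slope steepness (nm) of the sigmoidal oil-droplet cut-off.
#' @return A sensitivity [spectral_curve()] with values in `[0, 1]`.
#' @export
receptor_sensitivity <- function(rec, wavelengths = default_wavelengths(),
                                 template = c("a1", "gaussian"),
                                 droplet_slope = 6) {
  template <- match.arg(template)
  if (rec$lambda_max < min(wavelengths) || rec$lambda_max > max(wavelengths)) {
    stop(sprintf("lambda_max (%g nm) outside the wavelength grid",
                 rec$lambda_max))
  }
  s <- switch(template,
    a1 = a1_template(wavelengths, rec$lambda_max),
    gaussian = exp(-((wavelengths - rec$lambda_max)^2) / (2 * 60^2)))
  s <- s / max(s)
  if (!is.na(rec$lambda_cut)) {
    s <- s / (1 + exp(-(wavelengths - rec$lambda_cut) / droplet_slope))
  }
  if (!is.null(rec$media)) {
    m <- rec$media
    if (length(m$wavelengths) != length(wavelengths) ||
        any(m$wavelengths != wavelengths)) {
      stop("ocular media curve is not on the requested grid")
    }
    s <- s * m$values
  }
  spectral_curve(wavelengths, s, kind = "sensitivity")
}

#' Photoreceptor quantum catch of a reflectance
#'
#' Reflectance-referenced catch
#' `Q = integral(R I S) / integral(I S)` (trapezoidal), so a flat reflector
#' of reflectance r yields `Q = r` in every receptor under any illuminant.
#'
#' @param reflectance reflectance [spectral_curve()].
#' @param illuminant illuminant [spectral_curve()].
#' @param sensitivity sensitivity [spectral_curve()].
#' @return A single non-negative catch value.
#' @export
cone_catch <- function(reflectance, illuminant, sensitivity) {
  w <- stopifnot_same_grid(reflectance, illuminant, sensitivity)
  denom <- trapz(w, illuminant$values * sensitivity$values)
  if (denom <= 0) stop("illuminant x sensitivity integrates to zero")
  trapz(w, reflectance$values * illuminant$values * sensitivity$values) / denom
}

# catches of one reflectance through a receptor set -> named vector
receptor_catches <- function(reflectance, receptors, illuminant,
                             sensitivities = NULL) {
  if (is.null(sensitivities)) {
    sensitivities <- lapply(receptors, receptor_sensitivity,
                            wavelengths = reflectance$wavelengths)
  }
  vapply(sensitivities, function(s) cone_catch(reflectance, illuminant, s),
         numeric(1))
}

# polynomial feature expansion of linear camera channels (degree 1 or 2)
camera_features <- function(X, degree) {
  colnames(X) <- c("R", "G", "B")
  if (degree == 1L) return(X)
  cbind(X, R2 = X[, 1]^2, G2 = X[, 2]^2, B2 = X[, 3]^2,
        RG = X[, 1] * X[, 2], RB = X[, 1] * X[, 3], GB = X[, 2] * X[, 3])
}

#' Fit a regression map from camera channels to cone catches
#'
#' The field photographs behind this kind of analysis are RGB images, while
#' the quantity of interest is the catch of each avian receptor. This fits,
#' per receptor, a least-squares regression from noiseless linear camera
#' channel responses to true spectrally-computed catches over a training
#' set of reflectance spectra spanning the scene gamut, and records
#' held-out R-squared per receptor on a reserved split. The default is a
#' full quadratic in the three channels (`degree = 2`); `degree = 1` gives
#' a plain affine map. The UVS receptor is deliberately not part of the
#' mapped set: scenes here (like the stems and caterpillars that motivate
#' them) carry negligible UV information, and the opponent space
#' downstream is three-dimensional.
#'
#' @param spectra list of >= 20 reflectance [spectral_curve()]s spanning the
#'   scene gamut, e.g. from [scene_training_spectra()].
#' @param camera a [camera_model()].
#' @param receptors receptor set; the map is fitted for LWS, MWS, SWS and D.
#' @param illuminant illuminant [spectral_curve()].
#' @param degree polynomial degree of the channel features (1 or 2).
#' @param holdout fraction of spectra reserved for the R-squared diagnostic.
#' @param seed seed for the train/holdout shuffle.
#' @return An object of class `rgb_cone_map` with elements `coef`
#'   (features + intercept x 4 receptors), `degree` and `r_squared`
#'   (held-out, per receptor).
#' @export
fit_rgb_to_cone_map <- function(spectra, camera,
                                receptors = starling_receptors(),
                                illuminant = illuminant_spectrum("flat"),
                                degree = 2L, holdout = 0.25, seed = 1L) {
  if (length(spectra) < 20L) {
    stop("need at least 20 training spectra", call. = FALSE)
  }
  if (!degree %in% 1:2) stop("'degree' must be 1 or 2", call. = FALSE)
  targets <- c("LWS", "MWS", "SWS", "D")
  w <- spectra[[1]]$wavelengths
  sens <- lapply(receptors[targets], receptor_sensitivity, wavelengths = w)
  X <- t(vapply(spectra, camera_catch, numeric(3), camera = camera,
                illuminant = illuminant))
  P <- camera_features(X, degree)
  Y <- t(vapply(spectra, function(sp) {
    vapply(sens, function(s) cone_catch(sp, illuminant, s), numeric(1))
  }, numeric(length(targets))))
  colnames(Y) <- targets
  if (qr(cbind(1, X))$rank < 4L) {
    stop("training spectra are rank-deficient in camera space; ",
         "supply spectra with more spectral variety", call. = FALSE)
  }
  n <- length(spectra)
  withr::local_seed(seed)
  idx <- sample.int(n)
  n_hold <- max(1L, floor(holdout * n))
  hold <- idx[seq_len(n_hold)]
  train <- idx[-seq_len(n_hold)]
  coef <- matrix(NA_real_, ncol(P) + 1L, length(targets),
                 dimnames = list(c("(Intercept)", colnames(P)), targets))
  r2 <- stats::setNames(numeric(length(targets)), targets)
  for (tg in targets) {
    fit <- stats::lm.fit(cbind(1, P[train, , drop = FALSE]), Y[train, tg])
    coef[, tg] <- fit$coefficients
    pred <- cbind(1, P[hold, , drop = FALSE]) %*% coef[, tg]
    ss_res <- sum((Y[hold, tg] - pred)^2)
    ss_tot <- sum((Y[hold, tg] - mean(Y[hold, tg]))^2)
    r2[tg] <- 1 - ss_res / max(ss_tot, .Machine$double.eps)
  }
  structure(list(coef = coef, degree = as.integer(degree), r_squared = r2,
                 n_train = length(train), n_holdout = n_hold),
            class = "rgb_cone_map")
}

#' @export
print.rgb_cone_map <- function(x, ...) {
  cat(sprintf("<rgb_cone_map: degree-%d camera->cone transform>\n",
              x$degree %||% 1L))
  cat("held-out R-squared:",
      paste(sprintf("%s %.4f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  invisible(x)
}

#' Apply a camera-to-cone map to a linearized image
#'
#' Per-pixel polynomial transform from the three linear camera channels to
#' catches of LWS, MWS, SWS and D. Negative predictions (possible at noisy
#' dark pixels) are clipped to zero and counted.
#'
#' @param image a `linear_image` from [linearize()].
#' @param map an `rgb_cone_map` from [fit_rgb_to_cone_map()].
#' @return An object of class `cone_catch_image`: list with `catch`
#'   (h x w x 4 array, channels LWS/MWS/SWS/D), `valid` (logical matrix,
#'   inherited from the linear image), `ppl` (pixels per target length,
#'   carried through when present), `n_clipped` (count of clipped negative
#'   predictions) and `scene_id`.
#' @export
apply_map <- function(image, map) {
  stopifnot(inherits(image, "linear_image"), inherits(map, "rgb_cone_map"))
  d <- dim(image$linear)
  P <- camera_features(matrix(image$linear, ncol = 3L), map$degree %||% 1L)
  Q <- cbind(1, P) %*% map$coef
  n_clipped <- sum(Q < 0)
  Q[Q < 0] <- 0
  catch <- array(Q, dim = c(d[1], d[2], 4L),
                 dimnames = list(NULL, NULL, colnames(map$coef)))
  structure(list(catch = catch, valid = image$valid,
                 ppl = image$ppl, n_clipped = n_clipped,
                 scene_id = image$scene_id),
            class = "cone_catch_image")
}

# build a cone_catch_image directly from an array (internal)
cone_catch_image <- function(catch, valid = NULL, ppl = NULL,
                             scene_id = NA_character_, n_clipped = 0L) {
  stopifnot(length(dim(catch)) == 3L)
  if (is.null(valid)) valid <- matrix(TRUE, dim(catch)[1], dim(catch)[2])
  structure(list(catch = catch, valid = valid, ppl = ppl,
                 n_clipped = n_clipped, scene_id = scene_id),
            class = "cone_catch_image")
}

#' Opponent colour channels
#'
#' Collapses receptor catches into the three-dimensional colour space used
#' for the analysis, following the logic of perceptual opponent coding:
#' luminance from the double cone, red-green from the relative stimulation
#' of LWS vs MWS, yellow-blue from the relative stimulation of LWS+MWS vs
#' SWS. Normalized differences are used so that both chromatic channels are
#' bounded in `[-1, 1]` and invariant to overall intensity:
#' \deqn{L = Q_D,\quad RG = \frac{Q_L - Q_M}{Q_L + Q_M},\quad
#'       YB = \frac{Q_L + Q_M - Q_S}{Q_L + Q_M + Q_S}.}
#' Pixels whose catches are all (numerically) zero have no defined hue; they
#' are set to zero and flagged invalid so that sampling skips them.
#'
#' @param image a `cone_catch_image`.
#' @param eps denominator floor guarding against division by zero.
#' @return An object of class `opponent_image`: list with `channels`
#'   (h x w x 3 array, `L`, `RG`, `YB`), `valid`, `ppl`, `scene_id`.
#' @export
opponent_channels <- function(image, eps = 1e-9) {
  stopifnot(inherits(image, "cone_catch_image"))
  q <- image$catch
  ql <- q[, , "LWS"]; qm <- q[, , "MWS"]; qs <- q[, , "SWS"]
  lum <- q[, , "D"]
  dead <- (ql + qm) < eps | (ql + qm + qs) < eps
  rg <- (ql - qm) / pmax(ql + qm, eps)
  yb <- (ql + qm - qs) / pmax(ql + qm + qs, eps)
  rg[dead] <- 0
  yb[dead] <- 0
  channels <- array(c(lum, rg, yb), dim = c(dim(q)[1:2], 3L),
                    dimnames = list(NULL, NULL, c("L", "RG", "YB")))
  structure(list(channels = channels, valid = image$valid & !dead,
                 ppl = image$ppl, scene_id = image$scene_id),
            class = "opponent_image")
}
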