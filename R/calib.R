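#' Recover the camera tone curve from calibration patches
#'
#' Fits, per channel, an invertible power-law map from digital numbers to
#' linear reflectance, `DN = gain * r^(1/gamma)`, by least squares on the
#' log-log line `log DN = log gain + (1/gamma) log r` over the embedded
#' patches of known reflectance. At least three patches spanning the
#' reflectance range are required; patch data must be monotone (a brighter
#' patch must not yield a smaller digital number) and the fit is refused if
#' the log-scale residual RMS exceeds `max_rms`.
#'
#' @param dn_means numeric matrix (patches x 3 channels) of mean digital
#'   numbers per patch, or a vector recycled across channels. Real-valued
#'   means are accepted (e.g. averages over noisy patch pixels).
#' @param reflectances known patch reflectances in `(0, 1]`.
#' @param dn_max maximum representable digital number (for range checks).
#' @param max_rms refuse the fit if any channel's residual RMS (log DN
#'   scale) exceeds this bound.
#' @return An object of class `linearization_model`: per-channel `gain` and
#'   `gamma`, residual RMS per channel, and `dn_max`.
#' @export
fit_linearization <- function(dn_means, reflectances, dn_max = 255,
                              max_rms = 0.05) {
  if (is.null(dim(dn_means))) dn_means <- matrix(dn_means, ncol = 3L,
                                                 nrow = length(dn_means))
  n <- nrow(dn_means)
  if (n < 3L) {
    stop("need at least 3 calibration patches (fit is underdetermined)",
         call. = FALSE)
  }
  if (length(reflectances) != n) {
    stop("one reflectance per patch row is required", call. = FALSE)
  }
  if (any(reflectances <= 0 | reflectances > 1)) {
    stop("patch reflectances must lie in (0, 1]", call. = FALSE)
  }
  if (any(dn_means <= 0 | dn_means > dn_max)) {
    stop("patch digital numbers outside (0, dn_max]", call. = FALSE)
  }
  ord <- order(reflectances)
  for (ch in 1:3) {
    d <- dn_means[ord, ch]
    bad <- which(diff(d) <= 0)
    if (length(bad)) {
      stop(sprintf(
        "non-monotone patch data in channel %d: reflectance %.3g -> DN %.4g but %.3g -> DN %.4g",
        ch, reflectances[ord][bad[1]], d[bad[1]],
        reflectances[ord][bad[1] + 1], d[bad[1] + 1]), call. = FALSE)
    }
  }
  gain <- gamma <- rms <- numeric(3)
  lx <- log(reflectances)
  for (ch in 1:3) {
    ly <- log(dn_means[, ch])
    fit <- stats::lm.fit(cbind(1, lx), ly)
    b <- fit$coefficients
    gain[ch] <- exp(b[1])
    gamma[ch] <- 1 / b[2]
    rms[ch] <- sqrt(mean(fit$residuals^2))
  }
  if (any(rms > max_rms)) {
    stop(sprintf(
      "linearization fit rejected: residual RMS %.4g exceeds bound %.4g",
      max(rms), max_rms), call. = FALSE)
  }
  if (any(gamma <= 0)) stop("fitted map is not increasing", call. = FALSE)
  structure(list(gain = gain, gamma = gamma, residual_rms = rms,
                 dn_max = dn_max),
            class = "linearization_model")
}

#' @export
print.linearization_model <- function(x, ...) {
  cat(sprintf(
    "<linearization_model: gamma %s, gain %s, residual RMS %s>\n",
    paste(sprintf("%.4g", x$gamma), collapse = "/"),
    paste(sprintf("%.4g", x$gain), collapse = "/"),
    paste(sprintf("%.2g", x$residual_rms), collapse = "/")))
  invisible(x)
}

#' Mean digital numbers of the embedded calibration patches
#'
#' @param raw a `raw_image`.
#' @return list with `dn_means` (patches x 3 matrix), `reflectances`, and
#'   `grey_standard` (index of the 15% grey patch).
#' @export
extract_patch_dn <- function(raw) {
  stopifnot(inherits(raw, "raw_image"))
  dn_means <- t(vapply(raw$patches, function(p) {
    vapply(1:3, function(ch) mean(raw$dn[p$rows, p$cols, ch]), numeric(1))
  }, numeric(3)))
  list(dn_means = dn_means,
       reflectances = vapply(raw$patches, `[[`, numeric(1), "reflectance"),
       grey_standard = which(vapply(raw$patches, function(p)
         isTRUE(p$grey_standard), logical(1)))[1])
}

#' Linearize a raw image to reflectance units
#'
#' Inverts the fitted tone curve per pixel, `r = (DN / gain)^gamma`, then
#' rescales each channel so the 15% grey standard's patch mean is exactly
#' 0.15 (a von-Kries-style per-channel normalization to the single stated
#' reference). Saturated pixels (DN at full scale) have unbounded linear
#' values; they are flagged invalid and excluded from downstream sampling.
#'
#' @param raw a `raw_image` from [render_scene()].
#' @param model a `linearization_model` from [fit_linearization()].
#' @param ppl pixels-per-target-length carried to downstream stages
#'   (taken from a `scene_truth` when piping a full scene).
#' @return An object of class `linear_image`: `linear` (h x w x 3 double
#'   array in reflectance units), `valid` (logical matrix, FALSE at
#'   saturated pixels), `ppl`, `scene_id` and the model.
#' @export
linearize <- function(raw, model, ppl = NULL) {
  stopifnot(inherits(raw, "raw_image"), inherits(model, "linearization_model"))
  dn <- raw$dn
  if (any(dn < 0 | dn > model$dn_max)) {
    stop("digital numbers outside [0, dn_max]", call. = FALSE)
  }
  d <- dim(dn)
  lin <- array(0, dim = d)
  for (ch in 1:3) {
    lin[, , ch] <- (dn[, , ch] / model$gain[ch])^model$gamma[ch]
  }
  # grey-standard anchor
  pd <- extract_patch_dn(raw)
  gs <- pd$grey_standard
  if (!is.na(gs)) {
    for (ch in 1:3) {
      gmean <- mean((raw$dn[raw$patches[[gs]]$rows,
                            raw$patches[[gs]]$cols, ch] /
                       model$gain[ch])^model$gamma[ch])
      lin[, , ch] <- lin[, , ch] * (0.15 / gmean)
    }
  }
  saturated <- dn[, , 1] == model$dn_max | dn[, , 2] == model$dn_max |
    dn[, , 3] == model$dn_max
  structure(list(linear = lin, valid = !saturated, ppl = ppl,
                 scene_id = raw$scene_id, model = model),
            class = "linear_image")
}
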