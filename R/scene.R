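#' Synthetic scene configuration
#'
#' Describes one synthetic "photograph": an elongated elliptical striped
#' target (the caterpillar) on a stem-like background, with a strip of flat
#' calibration patches (including a 15% grey standard) along the top edge,
#' rendered through a [camera_model()]. Stripes run perpendicular to the
#' target's long axis. The scene is scaled by the target length in pixels,
#' which downstream stages use as the acuity unit.
#'
#' The background can either be an explicit spectrum (`background =
#' "green_stem"`) or the duty-cycle-weighted mean of the two stripe spectra
#' (`background = "mean"`), optionally displaced by a uniform additive
#' reflectance offset `delta` (clipped into `[0, 1]`). `delta = 0` with
#' `background = "mean"` is the fully mean-matched case: the colour the
#' stripes blend into at distance equals the background colour.
#'
#' @param width,height image size in pixels.
#' @param target_length,target_width ellipse axes in pixels.
#' @param stripe_period stripe period along the long axis, in pixels (>= 2).
#' @param duty fraction of each period that is orange, in `[0, 1]`.
#' @param orange_id,black_id stripe spectrum ids (see [scene_spectrum()]).
#' @param background `"mean"` or a spectrum id.
#' @param delta uniform additive offset applied to the background
#'   reflectance spectrum.
#' @param bg_heterogeneity_sd per-pixel multiplicative intensity variation
#'   of the background (standard deviation; 0 disables).
#' @param target_center `c(row, col)` of the ellipse centre, or `NULL` to
#'   centre it in the analysable region.
#' @param stripe_phase stripe phase offset in pixels.
#' @param patch_strip_height height (rows) of the excluded calibration strip.
#' @param patch_noise render calibration patches with camera noise? Default
#'   `FALSE`, so calibration recovery is exact.
#' @param seed RNG seed for noise and heterogeneity.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 256L, height = 240L,
                         target_length = 70, target_width = 19,
                         stripe_period = 10, duty = 0.5,
                         orange_id = "orange", black_id = "black",
                         background = "mean", delta = 0,
                         bg_heterogeneity_sd = 0.08,
                         target_center = NULL, stripe_phase = 0,
                         patch_strip_height = 18L, patch_noise = FALSE,
                         seed = 1L) {
  if (duty < 0 || duty > 1) stop("'duty' must be in [0, 1]", call. = FALSE)
  if (stripe_period < 2) stop("'stripe_period' must be >= 2 px", call. = FALSE)
  if (bg_heterogeneity_sd < 0) stop("'bg_heterogeneity_sd' must be >= 0")
  if (is.null(target_center)) {
    # low on the frame, clear of the calibration strip even under heavy blur
    target_center <- c(height - 50, width / 2)
  }
  cfg <- structure(list(
    width = as.integer(width), height = as.integer(height),
    target_length = target_length, target_width = target_width,
    stripe_period = stripe_period, duty = duty,
    orange_id = orange_id, black_id = black_id,
    background = background, delta = delta,
    bg_heterogeneity_sd = bg_heterogeneity_sd,
    target_center = target_center, stripe_phase = stripe_phase,
    patch_strip_height = as.integer(patch_strip_height),
    patch_noise = isTRUE(patch_noise), seed = as.integer(seed)),
    class = "scene_config")
  if (target_length > width || target_width > height - patch_strip_height) {
    stop("target does not fit inside the image", call. = FALSE)
  }
  cfg
}

# reflectances of the embedded calibration patches; the 0.15 entry is the
# grey standard used as the reflectance anchor.
default_patch_reflectances <- function() c(0.04, 0.10, 0.15, 0.30, 0.55, 0.85)

# patch geometry inside the excluded strip -> list of (reflectance, rows, cols)
patch_layout <- function(config) {
  refl <- default_patch_reflectances()
  n <- length(refl)
  side <- min(12L, config$patch_strip_height - 4L)
  gap <- floor((config$width - n * side) / (n + 1))
  lapply(seq_len(n), function(i) {
    c0 <- gap * i + side * (i - 1L) + 1L
    list(reflectance = refl[i],
         rows = seq(3L, 2L + side),
         cols = seq(c0, c0 + side - 1L),
         grey_standard = isTRUE(all.equal(refl[i], 0.15)))
  })
}

#' Render a synthetic scene
#'
#' Computes camera channel catches for every pixel from its reflectance
#' spectrum (orange stripe, black stripe, background, or a flat calibration
#' patch), applies the camera tone curve and noise, and quantizes to digital
#' numbers. Background pixels get an optional per-pixel multiplicative
#' intensity jitter emulating natural stem heterogeneity. Patches render
#' noiselessly by default. Deterministic given `config$seed`.
#'
#' @param config a [scene_config()].
#' @param camera a [camera_model()].
#' @param scene_id identifier stored in the outputs.
#' @return A list with elements `raw` (class `raw_image`: integer digital
#'   numbers `dn` (h x w x 3), the patch list, `bit_depth`, `scene_id`) and
#'   `truth` (class `scene_truth`: logical masks `target`, `background`,
#'   `excluded`, `orange` (which target pixels are orange), pixels per
#'   target length `ppl`, spectrum ids, seed and the config).
#' @export
render_scene <- function(config, camera = camera_model(),
                         scene_id = sprintf("scene%03d", config$seed)) {
  h <- config$height; w <- config$width
  withr::local_seed(config$seed)

  orange <- scene_spectrum(config$orange_id)
  black <- scene_spectrum(config$black_id)
  wl <- orange$wavelengths
  bg_vals <- if (identical(config$background, "mean")) {
    config$duty * orange$values + (1 - config$duty) * black$values
  } else {
    scene_spectrum(config$background, wavelengths = wl)$values
  }
  bg_vals <- pmin(pmax(bg_vals + config$delta, 0), 1)
  background <- spectral_curve(wl, bg_vals, kind = "reflectance")

  catch_orange <- camera_catch(orange, camera)
  catch_black <- camera_catch(black, camera)
  catch_bg <- camera_catch(background, camera)

  # geometry
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- config$target_center[1]; cx <- config$target_center[2]
  a <- config$target_length / 2; b <- config$target_width / 2
  target <- ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1
  excluded <- row <= config$patch_strip_height
  if (any(target & excluded)) stop("target overlaps the calibration strip")
  bg_mask <- !target & !excluded
  phase <- ((col - cx - config$stripe_phase) %% config$stripe_period)
  orange_mask <- target & (phase < config$duty * config$stripe_period)

  # per-pixel linear catches
  catch <- array(0, dim = c(h, w, 3L))
  f_bg <- if (config$bg_heterogeneity_sd > 0) {
    matrix(pmax(stats::rnorm(h * w, 1, config$bg_heterogeneity_sd), 0), h, w)
  } else {
    matrix(1, h, w)
  }
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[bg_mask] <- pmin(catch_bg[ch] * f_bg[bg_mask], 1)
    plane[target] <- catch_black[ch]
    plane[orange_mask] <- catch_orange[ch]
    catch[, , ch] <- plane
  }
  patches <- patch_layout(config)
  for (p in patches) {
    for (ch in 1:3) catch[p$rows, p$cols, ch] <- p$reflectance
  }

  dn <- camera_response(catch, camera, quantize = TRUE)
  if (!config$patch_noise && camera$noise_sd > 0) {
    clean <- camera_response(catch, camera, quantize = TRUE, noise_sd = 0)
    patch_px <- matrix(FALSE, h, w)
    for (p in patches) patch_px[p$rows, p$cols] <- TRUE
    for (ch in 1:3) {
      pl <- dn[, , ch]; cl <- clean[, , ch]
      pl[patch_px] <- cl[patch_px]
      dn[, , ch] <- pl
    }
  }
  storage.mode(dn) <- "integer"

  raw <- structure(list(dn = dn, patches = patches,
                        bit_depth = camera$bit_depth, scene_id = scene_id),
                   class = "raw_image")
  truth <- structure(list(target = target, background = bg_mask,
                          excluded = excluded, orange = orange_mask,
                          ppl = config$target_length,
                          spectra = list(orange = config$orange_id,
                                         black = config$black_id,
                                         background = config$background),
                          seed = config$seed, config = config,
                          scene_id = scene_id),
                     class = "scene_truth")
  list(raw = raw, truth = truth)
}

#' Generate a set of scenes with jittered geometry
#'
#' Renders `n_scenes` scenes from a shared configuration template, jittering
#' target length (±10%), centre position (±6 px) and stripe phase (uniform
#' over one period) with seeds derived deterministically from `base_seed`.
#' Each scene's seed is recorded in its truth object. At least two scenes
#' are required because downstream cross-validation leaves one scene out.
#'
#' @param config template [scene_config()].
#' @param n_scenes number of scenes (>= 2).
#' @param base_seed seed from which per-scene seeds and jitters derive.
#' @param camera a [camera_model()].
#' @return List of `n_scenes` elements, each a `list(raw, truth)`.
#' @export
make_scene_set <- function(config, n_scenes = 10L, base_seed = 1L,
                           camera = camera_model()) {
  if (n_scenes < 2L) {
    stop("'n_scenes' must be >= 2 (leave-one-out needs at least two scenes)",
         call. = FALSE)
  }
  seeds <- derive_seeds(base_seed, n_scenes)
  jit <- withr::with_seed(as.integer(base_seed) + 1L, list(
    len = stats::runif(n_scenes, 0.9, 1.1),
    drow = stats::runif(n_scenes, -6, 6),
    dcol = stats::runif(n_scenes, -6, 6),
    phase = stats::runif(n_scenes, 0, config$stripe_period)))
  lapply(seq_len(n_scenes), function(i) {
    cfg_i <- config
    cfg_i$target_length <- config$target_length * jit$len[i]
    cfg_i$target_center <- config$target_center + c(jit$drow[i], jit$dcol[i])
    cfg_i$stripe_phase <- jit$phase[i]
    cfg_i$seed <- seeds[i]
    render_scene(cfg_i, camera, scene_id = sprintf("scene%03d", i))
  })
}
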