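#' Viewing conditions
#'
#' Effective viewing distance is represented by Gaussian pattern blending of
#' the cone-catch image, not by a metric distance: `high` is the native
#' pixel resolution (close range, pattern fully resolved), `low` blurs with
#' a standard deviation of half a target length (beyond the resolution
#' limit of the stripes but with the target itself still resolvable), and
#' `average` replaces each region by its mean colour (the limiting case of
#' complete blending within target and background).
#'
#' @param label `"high"`, `"low"` or `"average"`.
#' @return An object of class `viewing_condition` with `label` and
#'   `sigma_tl` (blur sd in target-length units; `NA` for `average`).
#' @export
viewing_condition <- function(label = c("high", "low", "average")) {
  label <- match.arg(label)
  structure(list(label = label,
                 sigma_tl = switch(label, high = 0, low = 0.5, average = NA)),
            class = "viewing_condition")
}

# map i possibly outside 1..n back inside by half-sample symmetric reflection
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# 1D Gaussian kernel truncated at 4 sigma, normalized to sum 1
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# separable convolution of a matrix with reflective (edge-repeating) boundary
blur_matrix <- function(m, sigma) {
  if (sigma == 0) return(m)
  w <- gaussian_kernel(sigma)
  r <- (length(w) - 1L) / 2L
  conv_rows <- function(mat) {
    n <- nrow(mat)
    pad <- mat[reflect_index((1L - r):(n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (k in seq_along(w)) {
      out <- out + w[k] * pad[k:(k + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' Gaussian pattern blending
#'
#' Convolves each channel with an isotropic 2D Gaussian (kernel truncated at
#' 4 sigma, reflective boundary so region means are not darkened at edges).
#' `sigma_px = 0` returns the input unchanged. Accepts a plain matrix, a
#' 3D array, or a `cone_catch_image`.
#'
#' @param image matrix, h x w x c array, or `cone_catch_image`.
#' @param sigma_px blur standard deviation in pixels (>= 0, finite).
#' @return Blended object of the same class/shape.
#' @export
gaussian_blend <- function(image, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || !is.finite(sigma_px) ||
      sigma_px < 0) {
    stop("'sigma_px' must be a single finite value >= 0", call. = FALSE)
  }
  if (inherits(image, "cone_catch_image")) {
    out <- image
    for (ch in seq_len(dim(image$catch)[3])) {
      out$catch[, , ch] <- blur_matrix(image$catch[, , ch], sigma_px)
    }
    return(out)
  }
  if (is.matrix(image)) return(blur_matrix(image, sigma_px))
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3])) {
      out[, , ch] <- blur_matrix(image[, , ch], sigma_px)
    }
    return(out)
  }
  stop("'image' must be a matrix, 3D array or cone_catch_image",
       call. = FALSE)
}

#' Apply a viewing condition to a cone-catch image
#'
#' `high` is the identity; `low` blends with
#' `sigma_px = 0.5 x pixels-per-target-length`; `average` replaces every
#' target pixel by the per-channel mean over the target mask and every
#' background pixel by the mean over the background mask (computed per
#' image). Blending operates on cone catches; opponent channels are
#' computed afterwards, since optical blur physically precedes opponency.
#'
#' @param image a `cone_catch_image`.
#' @param truth the scene's `scene_truth` (supplies the masks and scale).
#' @param cond a [viewing_condition()] or its label.
#' @return A `cone_catch_image`; for `low` the attribute blur sigma (px) is
#'   recorded in element `sigma_px`.
#' @export
apply_condition <- function(image, truth, cond) {
  if (is.character(cond)) cond <- viewing_condition(cond)
  stopifnot(inherits(image, "cone_catch_image"),
            inherits(truth, "scene_truth"))
  out <- switch(cond$label,
    high = image,
    low = {
      ppl <- image$ppl %||% truth$ppl
      if (is.null(ppl) || ppl <= 0) {
        stop("pixels-per-target-length missing; cannot scale the blur")
      }
      b <- gaussian_blend(image, 0.5 * ppl)
      b$sigma_px <- 0.5 * ppl
      b
    },
    average = {
      avg <- image
      for (ch in seq_len(dim(image$catch)[3])) {
        plane <- image$catch[, , ch]
        plane[truth$target] <- mean(plane[truth$target])
        plane[truth$background] <- mean(plane[truth$background])
        avg$catch[, , ch] <- plane
      }
      avg
    },
    stop(sprintf("unknown viewing condition '%s'", cond$label)))
  out
}

# chessboard dilation of a logical mask by m pixels (separable shift-OR)
dilate_box <- function(mask, m) {
  if (m <= 0) return(mask)
  dilate_rows <- function(mk) {
    n <- nrow(mk)
    acc <- mk
    for (k in seq_len(min(m, n - 1L))) {
      acc[1:(n - k), ] <- acc[1:(n - k), ] | mk[(k + 1):n, ]
      acc[(k + 1):n, ] <- acc[(k + 1):n, ] | mk[1:(n - k), ]
    }
    acc
  }
  t(dilate_rows(t(dilate_rows(mask))))
}

#' Sample pixels for analysis
#'
#' Draws up to `n_max` pixels per class (target, background), uniformly
#' without replacement within each ground-truth mask, skipping invalid
#' pixels (saturated, undefined hue) and optionally any pixel within
#' `exclusion_margin_px` (chessboard distance) of the excluded region —
#' used under heavy blending, where values near the calibration patches are
#' contaminated by them. Deterministic given `seed`.
#'
#' @param image an `opponent_image`.
#' @param truth the scene's `scene_truth`.
#' @param n_max maximum pixels per class (default 1000); if a mask holds
#'   fewer valid pixels, all of them are taken.
#' @param seed RNG seed.
#' @param exclusion_margin_px margin around the excluded region to drop.
#' @return A data frame (`pixel_sample`) with columns `scene_id`, `class`,
#'   `L`, `RG`, `YB`, `row`, `col`; attribute `seed`.
#' @export
sample_pixels <- function(image, truth, n_max = 1000L, seed = 1L,
                          exclusion_margin_px = 0L) {
  stopifnot(inherits(image, "opponent_image"), inherits(truth, "scene_truth"))
  near_excl <- dilate_box(truth$excluded, as.integer(exclusion_margin_px))
  ch <- image$channels
  withr::local_seed(as.integer(seed))
  one_class <- function(mask, label) {
    ok <- mask & image$valid & !near_excl
    idx <- which(ok)
    if (!length(idx)) {
      stop(sprintf("no sampleable '%s' pixels in scene %s", label,
                   image$scene_id), call. = FALSE)
    }
    take <- min(as.integer(n_max), length(idx))
    sel <- sample(idx, take)
    rc <- arrayInd(sel, dim(mask))
    data.frame(scene_id = image$scene_id, class = label,
               L = ch[, , "L"][sel], RG = ch[, , "RG"][sel],
               YB = ch[, , "YB"][sel], row = rc[, 1], col = rc[, 2],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_class(truth$target, "target"),
               one_class(truth$background, "background"))
  if (any(!is.finite(as.matrix(out[, c("L", "RG", "YB")])))) {
    stop("non-finite feature values in sampled pixels", call. = FALSE)
  }
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("pixel_sample", "data.frame")
  out
}
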