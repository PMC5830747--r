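# Independent brute-force 2D Gaussian convolution: direct double sum over
# all kernel offsets with half-sample symmetric (edge-repeating) boundary.
# Written from the definition, independent of the package's separable path.
brute_force_blur <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  off <- seq(-r, r)
  w1 <- dnorm(off, sd = sigma)
  w1 <- w1 / sum(w1)
  k2 <- outer(w1, w1)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in seq_along(off)) {
        for (b in seq_along(off)) {
          acc <- acc + k2[a, b] * m[refl(i + off[a], nr), refl(j + off[b], nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# small, fast scene used by unit tests
tiny_scene_config <- function(...) {
  scene_config(width = 96L, height = 110L, target_length = 30,
               target_width = 12, stripe_period = 6,
               patch_strip_height = 14L, target_center = c(80, 48), ...)
}

quiet_camera <- function(...) camera_model(...)

# hand-built scene_truth for mask-level tests
toy_truth <- function(h, w, target, excluded = matrix(FALSE, h, w),
                      ppl = 10, scene_id = "toy") {
  structure(list(target = target, background = !target & !excluded,
                 excluded = excluded, orange = target & FALSE,
                 ppl = ppl, seed = 0L, scene_id = scene_id),
            class = "scene_truth")
}

toy_opponent <- function(channels, valid = NULL, ppl = 10,
                         scene_id = "toy") {
  if (is.null(valid)) valid <- matrix(TRUE, dim(channels)[1], dim(channels)[2])
  structure(list(channels = channels, valid = valid, ppl = ppl,
                 scene_id = scene_id),
            class = "opponent_image")
}

# pixel samples where both classes share one distribution (null case)
null_samples <- function(n_scenes, n_px, seed) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_scenes), function(s) {
    data.frame(scene_id = sprintf("s%02d", s),
               class = rep(c("target", "background"), each = n_px),
               L = rnorm(2 * n_px), RG = rnorm(2 * n_px),
               YB = rnorm(2 * n_px), stringsAsFactors = FALSE)
  })))
}

# cleanly separable samples: L differs by 10 sd between classes
separable_samples <- function(n_scenes, n_px, seed) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_scenes), function(s) {
    data.frame(scene_id = sprintf("s%02d", s),
               class = rep(c("target", "background"), each = n_px),
               L = c(rnorm(n_px, 1, 0.1), rnorm(n_px, 0, 0.1)),
               RG = rnorm(2 * n_px, 0, 0.1),
               YB = rnorm(2 * n_px, 0, 0.1), stringsAsFactors = FALSE)
  })))
}
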