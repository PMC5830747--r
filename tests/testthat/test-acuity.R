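test_that("zero sigma is the identity and constants are fixed points", {
  withr::with_seed(1, m <- matrix(runif(20 * 15), 20, 15))
  expect_identical(gaussian_blend(m, 0), m)
  flat <- matrix(3.7, 12, 9)
  expect_equal(gaussian_blend(flat, 2.5), flat, tolerance = 1e-12)
  expect_error(gaussian_blend(m, NaN), "finite")
  expect_error(gaussian_blend(m, -1), "finite")
})

test_that("separable blending matches the brute-force double sum", {
  withr::with_seed(42, m <- matrix(runif(16 * 16), 16, 16))
  expect_lt(max(abs(gaussian_blend(m, 1.5) - brute_force_blur(m, 1.5))),
            1e-10)
})

test_that("blending is linear and preserves the global mean", {
  withr::with_seed(5, {
    x <- matrix(runif(18 * 14), 18, 14)
    y <- matrix(runif(18 * 14), 18, 14)
  })
  expect_lt(max(abs(gaussian_blend(2 * x - 3 * y, 2.2) -
                      (2 * gaussian_blend(x, 2.2) - 3 * gaussian_blend(y, 2.2)))),
            1e-10)
  for (s in c(0.8, 3, 7)) {
    expect_equal(mean(gaussian_blend(x, s)), mean(x), tolerance = 1e-6)
  }
})

test_that("viewing conditions branch correctly", {
  cam <- camera_model(noise_sd = 0)
  sc <- render_scene(tiny_scene_config(seed = 11, bg_heterogeneity_sd = 0),
                     cam)
  pd <- extract_patch_dn(sc$raw)
  lin <- linearize(sc$raw, fit_linearization(pd$dn_means, pd$reflectances),
                   ppl = sc$truth$ppl)
  cc <- apply_map(lin, fit_rgb_to_cone_map(random_smooth_spectra(40, seed = 3),
                                           cam, seed = 3))
  high <- apply_condition(cc, sc$truth, viewing_condition("high"))
  expect_identical(high$catch, cc$catch)
  avg <- apply_condition(cc, sc$truth, viewing_condition("average"))
  for (ch in 1:4) {
    expect_equal(stats::var(avg$catch[, , ch][sc$truth$target]), 0)
    expect_equal(stats::var(avg$catch[, , ch][sc$truth$background]), 0)
  }
  expect_error(apply_condition(cc, sc$truth,
                               structure(list(label = "far"),
                                         class = "viewing_condition")),
               "unknown viewing condition")
})

test_that("heavy blending pulls target means towards the background", {
  cam <- camera_model(noise_sd = 0)
  sc <- render_scene(tiny_scene_config(seed = 13, bg_heterogeneity_sd = 0,
                                       delta = 0), cam)
  pd <- extract_patch_dn(sc$raw)
  lin <- linearize(sc$raw, fit_linearization(pd$dn_means, pd$reflectances),
                   ppl = sc$truth$ppl)
  cc <- apply_map(lin, fit_rgb_to_cone_map(random_smooth_spectra(60, seed = 5),
                                           cam, seed = 5))
  low <- apply_condition(cc, sc$truth, viewing_condition("low"))
  expect_equal(low$sigma_px, 0.5 * sc$truth$ppl)
  # keep clear of the calibration strip, as the sampling margin does
  far <- row(sc$truth$target) >= 75
  tmask <- sc$truth$target & far
  bmask <- sc$truth$background & far
  for (ch in 1:4) {
    gap_high <- abs(mean(cc$catch[, , ch][tmask]) -
                      mean(cc$catch[, , ch][bmask]))
    gap_low <- abs(mean(low$catch[, , ch][tmask]) -
                     mean(low$catch[, , ch][bmask]))
    expect_lt(gap_low, gap_high)
  }
})

test_that("between-region separation is non-increasing in sigma", {
  cam <- camera_model(noise_sd = 0)
  # a stem background gives a real initial separation whose attenuation is
  # measurable; on exactly mean-matched scenes it starts at the numerical
  # floor where boundary exchange dominates
  sc <- render_scene(tiny_scene_config(seed = 17, bg_heterogeneity_sd = 0,
                                       background = "green_stem"), cam)
  pd <- extract_patch_dn(sc$raw)
  lin <- linearize(sc$raw, fit_linearization(pd$dn_means, pd$reflectances),
                   ppl = sc$truth$ppl)
  cc <- apply_map(lin, fit_rgb_to_cone_map(random_smooth_spectra(60, seed = 5),
                                           cam, seed = 5))
  sigmas <- c(0, 2, 5, 10, 15)
  far <- row(sc$truth$target) >= 75
  tmask <- sc$truth$target & far
  bmask <- sc$truth$background & far
  blurred <- lapply(sigmas, function(s) gaussian_blend(cc, s))
  for (ch in 1:4) {
    gaps <- vapply(blurred, function(b) {
      abs(mean(b$catch[, , ch][tmask]) - mean(b$catch[, , ch][bmask]))
    }, numeric(1))
    expect_true(all(diff(gaps) <= 1e-4 * gaps[1]))
  }
})

test_that("pixel sampling is exhaustive, unique and deterministic", {
  h <- 40; w <- 50
  target <- matrix(FALSE, h, w); target[10:20, 10:20] <- TRUE
  truth <- toy_truth(h, w, target)
  withr::with_seed(3, ch <- array(runif(h * w * 3), dim = c(h, w, 3),
                                  dimnames = list(NULL, NULL,
                                                  c("L", "RG", "YB"))))
  opp <- toy_opponent(ch)
  s1 <- sample_pixels(opp, truth, n_max = 1000, seed = 6)
  # 11 x 11 = 121 target pixels: all taken; background capped at n_max
  expect_equal(sum(s1$class == "target"), 121)
  expect_equal(sum(s1$class == "background"), 1000)
  key <- paste(s1$class, s1$row, s1$col)
  expect_false(any(duplicated(key)))
  s2 <- sample_pixels(opp, truth, n_max = 1000, seed = 6)
  expect_identical(s1, s2)
  s3 <- sample_pixels(opp, truth, n_max = 1000, seed = 7)
  expect_false(identical(s1, s3))
})

test_that("sampling respects masks, validity and the exclusion margin", {
  h <- 30; w <- 30
  target <- matrix(FALSE, h, w); target[20:25, 5:26] <- TRUE
  excl <- matrix(FALSE, h, w); excl[1:4, ] <- TRUE
  truth <- toy_truth(h, w, target, excluded = excl)
  ch <- array(0.5, dim = c(h, w, 3),
              dimnames = list(NULL, NULL, c("L", "RG", "YB")))
  valid <- matrix(TRUE, h, w); valid[22, 10] <- FALSE
  opp <- toy_opponent(ch, valid = valid)
  s <- sample_pixels(opp, truth, n_max = 1e4, seed = 2,
                     exclusion_margin_px = 6)
  expect_false(any(s$row <= 10 & s$class == "background"))
  expect_false(any(s$row == 22 & s$col == 10))
  # an all-excluded class errors with the scene named
  truth2 <- toy_truth(h, w, target, excluded = excl)
  truth2$target[] <- FALSE
  expect_error(sample_pixels(opp, truth2, seed = 1), "toy")
})
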