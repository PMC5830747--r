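test_that("scene masks partition the analysed pixels", {
  sc <- render_scene(tiny_scene_config(seed = 5))
  tr <- sc$truth
  expect_false(any(tr$target & tr$background))
  expect_false(any(tr$target & tr$excluded))
  expect_false(any(tr$background & tr$excluded))
  expect_true(all(tr$target | tr$background | tr$excluded))
  expect_gt(sum(tr$target), 0)
  expect_gt(tr$ppl, 0)
})

test_that("rendering is deterministic given the seed", {
  cfg <- tiny_scene_config(seed = 42)
  a <- render_scene(cfg)
  b <- render_scene(cfg)
  expect_identical(a$raw$dn, b$raw$dn)
  expect_identical(a$truth$target, b$truth$target)
})

test_that("zero duty cycle renders every target pixel as the black spectrum", {
  cam <- camera_model(noise_sd = 0)
  sc <- render_scene(tiny_scene_config(seed = 2, duty = 0,
                                       bg_heterogeneity_sd = 0), cam)
  black_dn <- camera_response(camera_catch(scene_spectrum("black"), cam),
                              cam, quantize = TRUE)
  for (ch in 1:3) {
    expect_true(all(sc$raw$dn[, , ch][sc$truth$target] == black_dn[ch]))
  }
  expect_false(any(sc$truth$orange))
})

test_that("stripe area fraction tracks the duty cycle within quantization", {
  for (duty in c(0.3, 0.5, 0.7)) {
    cfg <- tiny_scene_config(seed = 7, duty = duty)
    sc <- render_scene(cfg)
    frac <- sum(sc$truth$orange) / sum(sc$truth$target)
    expect_lt(abs(frac - duty), cfg$stripe_period / cfg$target_length)
  }
})

test_that("area-weighted mean target spectrum matches the duty-weighted mix", {
  cfg <- tiny_scene_config(seed = 9, duty = 0.5)
  sc <- render_scene(cfg)
  orange <- scene_spectrum("orange")
  black <- scene_spectrum("black")
  n_o <- sum(sc$truth$orange)
  n_b <- sum(sc$truth$target) - n_o
  mean_spec <- (n_o * orange$values + n_b * black$values) / (n_o + n_b)
  mix <- 0.5 * (orange$values + black$values)
  quant_err <- cfg$stripe_period / cfg$target_length
  expect_lt(max(abs(mean_spec - mix)),
            quant_err * max(abs(orange$values - black$values)))
})

test_that("grey-standard and patch digital numbers rise with reflectance", {
  sc <- render_scene(tiny_scene_config(seed = 3))
  pd <- extract_patch_dn(sc$raw)
  ord <- order(pd$reflectances)
  for (ch in 1:3) expect_true(all(diff(pd$dn_means[ord, ch]) > 0))
  expect_equal(pd$reflectances[pd$grey_standard], 0.15)
})

test_that("with gamma 1 and no noise the camera is linear pre-clip", {
  cam <- camera_model(gamma = 1, noise_sd = 0, gain = 100)
  catch <- array(runif(60, 0, 0.5), dim = c(4, 5, 3))
  expect_equal(camera_response(2 * catch, cam, quantize = FALSE),
               2 * camera_response(catch, cam, quantize = FALSE),
               tolerance = 1e-12)
})

test_that("a target larger than the image is rejected", {
  expect_error(scene_config(width = 64, height = 64, target_length = 100),
               "does not fit")
})

test_that("scene sets have distinct seeds, jittered geometry, and repeat", {
  cfg <- tiny_scene_config()
  set1 <- make_scene_set(cfg, n_scenes = 4, base_seed = 10)
  expect_length(set1, 4)
  seeds <- vapply(set1, function(s) s$truth$seed, integer(1))
  expect_length(unique(seeds), 4)
  lens <- vapply(set1, function(s) s$truth$ppl, numeric(1))
  expect_gt(length(unique(lens)), 1)
  set2 <- make_scene_set(cfg, n_scenes = 4, base_seed = 10)
  expect_identical(lapply(set1, function(s) s$raw$dn),
                   lapply(set2, function(s) s$raw$dn))
  expect_error(make_scene_set(cfg, n_scenes = 1), "leave-one-out|>= 2")
})
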