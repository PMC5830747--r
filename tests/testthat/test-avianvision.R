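test_that("pigment templates peak at lambda_max and stay within [0, 1]", {
  bare <- receptor("X", 500, NA_real_, media = NULL)
  s <- receptor_sensitivity(bare)
  expect_equal(s$wavelengths[which.max(s$values)], 500)
  expect_true(all(s$values >= 0 & s$values <= 1))
  for (rec in starling_receptors()) {
    sv <- receptor_sensitivity(rec)
    expect_true(all(sv$values >= 0 & sv$values <= 1))
  }
  expect_error(receptor_sensitivity(receptor("bad", 900, NA_real_, NULL)),
               "outside the wavelength grid")
})

test_that("a long-pass oil droplet shifts the LWS peak beyond lambda_max", {
  lws <- receptor("LWS", 563, 570, media = NULL)
  s <- receptor_sensitivity(lws)
  expect_gt(s$wavelengths[which.max(s$values)], 563)
})

test_that("cone catches are reflectance-referenced", {
  recs <- starling_receptors()
  for (ill in list(illuminant_spectrum("flat"), illuminant_spectrum("daylight"))) {
    for (rec in recs) {
      s <- receptor_sensitivity(rec)
      expect_equal(cone_catch(make_spectrum("flat", r = 0.15), ill, s), 0.15,
                   tolerance = 1e-12)
      expect_equal(cone_catch(make_spectrum("flat", r = 1), ill, s), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("the orange stripe stimulates LWS more than MWS", {
  ill <- illuminant_spectrum("flat")
  recs <- starling_receptors()
  q_l <- cone_catch(scene_spectrum("orange"), ill,
                    receptor_sensitivity(recs$LWS))
  q_m <- cone_catch(scene_spectrum("orange"), ill,
                    receptor_sensitivity(recs$MWS))
  expect_gt(q_l, q_m)
})

test_that("mismatched wavelength grids are rejected", {
  a <- make_spectrum("flat", r = 0.5)
  b <- make_spectrum("flat", r = 0.5, wavelengths = seq(300, 700, by = 2))
  expect_error(cone_catch(a, b, a), "common wavelength grid")
})

test_that("camera matched to the cone templates maps back onto itself", {
  recs <- starling_receptors()
  sens <- lapply(recs[c("LWS", "MWS", "SWS")], receptor_sensitivity)
  cam <- camera_model(sensitivities = unname(sens), noise_sd = 0)
  map <- fit_rgb_to_cone_map(random_smooth_spectra(60, seed = 8), cam,
                             degree = 1L, seed = 8)
  expect_true(all(map$r_squared[c("LWS", "MWS", "SWS")] > 0.999))
  # channel weights are (near) a permutation identity for the matched cones
  w <- abs(map$coef[-1, c("LWS", "MWS", "SWS")])
  expect_equal(unname(apply(w, 2, which.max)), 1:3)
})

test_that("degenerate training sets are rejected", {
  cam <- camera_model(noise_sd = 0)
  flats <- lapply(seq(0.1, 0.9, length.out = 25),
                  function(r) make_spectrum("flat", r = r))
  expect_error(fit_rgb_to_cone_map(flats, cam), "rank-deficient")
  expect_error(fit_rgb_to_cone_map(flats[1:5], cam), "at least 20")
})

test_that("mapped catches agree with the direct spectral pathway", {
  # 16-bit sensor so quantization does not confound the map comparison
  cam <- camera_model(noise_sd = 0, gain = 65535, bit_depth = 16L)
  sc <- render_scene(tiny_scene_config(seed = 6, bg_heterogeneity_sd = 0),
                     cam)
  pd <- extract_patch_dn(sc$raw)
  lmod <- fit_linearization(pd$dn_means, pd$reflectances, dn_max = cam$dn_max)
  lin <- linearize(sc$raw, lmod, ppl = sc$truth$ppl)
  map <- fit_rgb_to_cone_map(scene_training_spectra(200, seed = 2), cam,
                             seed = 2)
  cc <- apply_map(lin, map)
  ill <- illuminant_spectrum("flat")
  recs <- starling_receptors()[c("LWS", "MWS", "SWS", "D")]
  specs <- list(orange = scene_spectrum("orange"),
                black = scene_spectrum("black"))
  for (i in seq_along(recs)) {
    truth_o <- cone_catch(specs$orange, ill, receptor_sensitivity(recs[[i]]))
    got_o <- mean(cc$catch[, , i][sc$truth$orange])
    expect_lt(abs(got_o / truth_o - 1), 0.05)
    truth_b <- cone_catch(specs$black, ill, receptor_sensitivity(recs[[i]]))
    got_b <- mean(cc$catch[, , i][sc$truth$target & !sc$truth$orange])
    expect_lt(abs(got_b / truth_b - 1), 0.05)
  }
  # grey standard pixels land near 0.15 in every receptor
  gp <- sc$raw$patches[[pd$grey_standard]]
  for (i in seq_along(recs)) {
    expect_equal(mean(cc$catch[gp$rows, gp$cols, i]), 0.15, tolerance = 0.01)
  }
})

test_that("opponent channels follow the normalized-difference definitions", {
  q <- array(0, dim = c(1, 3, 4), dimnames = list(NULL, NULL,
                                                  c("LWS", "MWS", "SWS", "D")))
  q[1, 1, ] <- c(0.6, 0.2, 0.1, 0.3)
  q[1, 2, ] <- c(0.25, 0.25, 0.1, 0.5)   # Q_L = Q_M
  q[1, 3, ] <- c(1.2, 0.4, 0.2, 0.6)     # row 1 scaled by 2
  opp <- opponent_channels(stripeblend:::cone_catch_image(q))
  expect_equal(as.numeric(opp$channels[1, 1, "RG"]), 0.5)
  expect_equal(as.numeric(opp$channels[1, 1, "YB"]), 0.7 / 0.9,
               tolerance = 1e-12)
  expect_equal(as.numeric(opp$channels[1, 1, "L"]), 0.3)
  expect_equal(as.numeric(opp$channels[1, 2, "RG"]), 0)
  # positive scaling leaves the chromatic channels unchanged
  expect_equal(opp$channels[1, 3, c("RG", "YB")],
               opp$channels[1, 1, c("RG", "YB")], tolerance = 1e-12)
})

test_that("all-zero catch pixels are flagged and excluded from sampling", {
  q <- array(0.2, dim = c(4, 4, 4), dimnames = list(NULL, NULL,
                                                    c("LWS", "MWS", "SWS", "D")))
  q[2, 2, ] <- 0
  opp <- opponent_channels(stripeblend:::cone_catch_image(q))
  expect_false(opp$valid[2, 2])
  expect_true(opp$valid[1, 1])
  expect_equal(as.numeric(opp$channels[2, 2, "RG"]), 0)
})

test_that("the discrimination features carry no UV channel", {
  sc <- render_scene(tiny_scene_config(seed = 1))
  pd <- extract_patch_dn(sc$raw)
  lmod <- fit_linearization(pd$dn_means, pd$reflectances)
  lin <- linearize(sc$raw, lmod, ppl = sc$truth$ppl)
  map <- fit_rgb_to_cone_map(random_smooth_spectra(40, seed = 4),
                             camera_model(), seed = 4)
  expect_false("UVS" %in% colnames(map$coef))
  opp <- opponent_channels(apply_map(lin, map))
  expect_identical(dimnames(opp$channels)[[3]], c("L", "RG", "YB"))
  samp <- sample_pixels(opp, sc$truth, n_max = 50, seed = 1)
  expect_true(all(c("L", "RG", "YB") %in% names(samp)))
  expect_false(any(grepl("UV", names(samp))))
})
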