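test_that("the fitted coefficient follows the direction of separation", {
  samp <- separable_samples(4, 200, seed = 1)
  m <- fit_binomial_mixed(samp)
  expect_gt(m$coef["L"], 0)
  expect_true(all(is.finite(m$coef)))
})

test_that("held-out prediction is population-level and well calibrated", {
  m <- structure(list(coef = c(`(Intercept)` = 0, L = 0, RG = 0, YB = 0),
                      center = c(L = 1, RG = 2, YB = 3),
                      scale = c(L = 1, RG = 1, YB = 1),
                      re_var = NA_real_, method = "glm", flags = character(0),
                      features = c("L", "RG", "YB")),
                 class = "discrim_model")
  at_mean <- data.frame(L = 1, RG = 2, YB = 3)
  expect_equal(predict_heldout(m, at_mean)$prob, 0.5)
  # logistic outputs stay strictly inside (0, 1)
  m$coef <- c(`(Intercept)` = 2, L = 5, RG = -3, YB = 1)
  big <- data.frame(L = c(-3, 4), RG = c(4, -1), YB = c(1, 4))
  p <- predict_heldout(m, big)$prob
  expect_true(all(p > 0 & p < 1))
  expect_error(predict_heldout(m, data.frame(L = 1, RG = 2)), "missing feature")
})

test_that("separable features give perfect held-out sensitivity", {
  samp <- separable_samples(4, 150, seed = 3)
  res <- loocv_sensitivity(samp, condition = "separable")
  expect_equal(res$pooled_misclassification, 0)
  expect_equal(res$mean_sensitivity, 1)
  expect_equal(nrow(res$folds), 4)
})

test_that("one fold per scene and structural errors are raised", {
  samp <- separable_samples(5, 60, seed = 4)
  res <- loocv_sensitivity(samp)
  expect_equal(res$n_scenes, 5)
  expect_equal(sort(res$folds$scene_id), sort(unique(samp$scene_id)))
  expect_error(loocv_sensitivity(samp[samp$scene_id == "s01", ]),
               "at least 2")
  one_class <- samp
  one_class <- one_class[!(one_class$scene_id == "s02" &
                             one_class$class == "target"), ]
  expect_error(loocv_sensitivity(one_class), "lack one of the classes")
})

test_that("pooled misclassification is invariant to scene order", {
  samp <- withr::with_seed(9, {
    s <- null_samples(4, 80, seed = 9)
    s$L <- s$L + 0.4 * (s$class == "target")
    s
  })
  res1 <- loocv_sensitivity(samp)
  perm <- samp[order(rev(samp$scene_id), samp$class), ]
  res2 <- loocv_sensitivity(perm)
  expect_equal(res2$pooled_misclassification, res1$pooled_misclassification)
})

test_that("feature translation before standardization changes nothing", {
  samp <- separable_samples(3, 100, seed = 5)
  shifted <- samp
  shifted$L <- shifted$L + 100
  shifted$RG <- shifted$RG - 7
  shifted$YB <- shifted$YB + 0.5
  m1 <- fit_binomial_mixed(samp)
  m2 <- fit_binomial_mixed(shifted)
  test <- samp[samp$scene_id == "s01", ]
  test_sh <- shifted[shifted$scene_id == "s01", ]
  expect_equal(predict_heldout(m2, test_sh)$prob,
               predict_heldout(m1, test)$prob, tolerance = 1e-6)
})

test_that("degenerate random-effect structure falls back and is recorded", {
  # constant features per scene-class with separable classes: the scene
  # variance collapses and/or separation triggers the ridge fallback
  samp <- do.call(rbind, lapply(1:4, function(s) {
    data.frame(scene_id = sprintf("s%02d", s),
               class = rep(c("target", "background"), each = 50),
               L = rep(c(1, 0), each = 50),
               RG = 0, YB = 0, stringsAsFactors = FALSE)
  }))
  m <- fit_binomial_mixed(samp)
  expect_true(m$method %in% c("glm", "ridge"))
  expect_gt(length(m$flags), 0)
  pred <- predict_heldout(m, samp[samp$scene_id == "s01", ])
  expect_true(all(pred$label[pred$class == "target"] == "target"))
})
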