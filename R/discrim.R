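#' Fit a binomial mixed model for target/background discrimination
#'
#' Logistic model with response `class == "target"`, fixed effects the
#' standardized opponent features (`L`, `RG`, `YB`) and a random intercept
#' per scene, fitted by Laplace-approximate maximum likelihood
#' (\code{lme4::glmer}). Standardization parameters come from the training
#' data only and are stored with the model, so held-out predictions never
#' leak information. Two guarded fallbacks, both recorded in the returned
#' object: if the random-intercept variance collapses to (numerically)
#' zero or the mixed fit fails, the model is refitted as a plain logistic
#' regression; if the classes are (quasi-)separable — coefficients
#' diverging or fitted probabilities saturating — a small ridge penalty is
#' applied instead (\code{glmnet}, alpha 0).
#'
#' Identical feature rows are aggregated into weighted binomial rows before
#' fitting; this is likelihood-equivalent and makes degenerate inputs (e.g.
#' region-mean colours, which are constant within a scene) fast and stable.
#'
#' @param train a `pixel_sample` data frame covering >= 2 scenes, both
#'   classes present in each.
#' @param features feature column names.
#' @param ridge_lambda ridge penalty used by the separation fallback.
#' @return An object of class `discrim_model`: `coef` (intercept + one per
#'   feature, on the standardized scale), `center`/`scale`, `re_var`
#'   (random-intercept variance; `NA` for fallback fits), `method` (one of
#'   `"glmm"`, `"glm"`, `"ridge"`), `flags`.
#' @export
fit_binomial_mixed <- function(train, features = c("L", "RG", "YB"),
                               ridge_lambda = 1e-3) {
  scenes <- unique(train$scene_id)
  if (length(scenes) < 2L) {
    stop("need at least 2 training scenes", call. = FALSE)
  }
  both <- tapply(train$class, train$scene_id,
                 function(cl) length(unique(cl)) == 2L)
  if (!all(both)) {
    stop(sprintf("training scene(s) %s lack one of the classes",
                 paste(names(both)[!both], collapse = ", ")), call. = FALSE)
  }
  y <- as.integer(train$class == "target")
  X <- as.matrix(train[, features, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  flags <- character(0)
  if (any(scale_ == 0)) {
    flags <- c(flags, "constant_feature")
    scale_[scale_ == 0] <- 1
  }
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")

  # aggregate duplicate rows into weighted binomial observations
  key <- do.call(paste, c(list(train$scene_id, y),
                          lapply(seq_len(ncol(Z)), function(j) Z[, j])))
  first <- !duplicated(key)
  wt <- as.vector(table(factor(key, levels = key[first])))
  dat <- data.frame(y = y[first], Z[first, , drop = FALSE],
                    scene_id = train$scene_id[first], w = wt)

  form <- stats::as.formula(paste("y ~", paste(features, collapse = " + "),
                                  "+ (1 | scene_id)"))
  coefs <- NULL; re_var <- NA_real_; method <- "glmm"
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(form, data = dat, family = stats::binomial,
                  weights = w))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    re_var <- as.numeric(lme4::VarCorr(fit)$scene_id[1])
    if (isTRUE(lme4::isSingular(fit, tol = 1e-6)) || re_var < 1e-8) {
      flags <- c(flags, "re_variance_collapsed")
      fit <- NULL
    } else {
      coefs <- lme4::fixef(fit)
    }
  } else {
    flags <- c(flags, "glmm_failed")
  }
  if (is.null(coefs)) {
    method <- "glm"
    sep <- FALSE
    withCallingHandlers(
      gfit <- stats::glm(stats::as.formula(
        paste("y ~", paste(features, collapse = " + "))),
        data = dat, family = stats::binomial, weights = w),
      warning = function(w_) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w_))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- stats::coef(gfit)
    if (sep || any(abs(coefs[-1]) > 15)) {
      method <- "ridge"
      flags <- c(flags, "separation_ridge")
      gn <- suppressWarnings(
        glmnet::glmnet(as.matrix(dat[, features, drop = FALSE]),
                       factor(dat$y, levels = 0:1),
                       family = "binomial", alpha = 0,
                       lambda = ridge_lambda, weights = dat$w,
                       standardize = FALSE))
      cf <- as.numeric(stats::coef(gn))
      coefs <- stats::setNames(cf, c("(Intercept)", features))
    }
    re_var <- NA_real_
  } else if (any(abs(coefs[-1]) > 15)) {
    # mixed fit converged but to a (quasi-)separated solution
    method <- "ridge"
    flags <- c(flags, "separation_ridge")
    gn <- suppressWarnings(
      glmnet::glmnet(as.matrix(dat[, features, drop = FALSE]),
                     factor(dat$y, levels = 0:1),
                     family = "binomial", alpha = 0,
                     lambda = ridge_lambda, weights = dat$w,
                     standardize = FALSE))
    cf <- as.numeric(stats::coef(gn))
    coefs <- stats::setNames(cf, c("(Intercept)", features))
  }
  if (any(!is.finite(coefs))) {
    stop("discrimination model failed to converge to finite coefficients",
         call. = FALSE)
  }
  structure(list(coef = coefs, center = center, scale = scale_,
                 re_var = re_var, method = method, flags = flags,
                 features = features),
            class = "discrim_model")
}

#' @export
print.discrim_model <- function(x, ...) {
  cat(sprintf("<discrim_model (%s): %s; RE var %.4g%s>\n", x$method,
              paste(sprintf("%s=%.3f", names(x$coef), x$coef),
                    collapse = ", "),
              x$re_var,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Predict held-out pixels
#'
#' Population-level prediction: the held-out scene was never seen during
#' training, so its random intercept is set to zero. Features are
#' standardized with the training parameters stored in the model.
#'
#' @param model a `discrim_model`.
#' @param rows a `pixel_sample` data frame.
#' @param threshold classification threshold on the target probability.
#' @return `rows` with added columns `prob` and `label`.
#' @export
predict_heldout <- function(model, rows, threshold = 0.5) {
  stopifnot(inherits(model, "discrim_model"))
  if (!all(model$features %in% names(rows))) {
    stop("missing feature columns in prediction rows", call. = FALSE)
  }
  X <- as.matrix(rows[, model$features, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  eta <- model$coef[1] + as.vector(Z %*% model$coef[-1])
  rows$prob <- stats::plogis(eta)
  rows$label <- ifelse(rows$prob > threshold, "target", "background")
  rows
}

#' Leave-one-scene-out cross-validated discrimination
#'
#' One fold per scene: the model is trained on all other scenes and
#' evaluated on the held-out scene's pixels at the given threshold.
#' Reports per-fold confusion counts, sensitivity (proportion of target
#' pixels classified as target) and specificity, plus the pooled
#' misclassification of target pixels, `sum(FN) / sum(TP + FN)`
#' (count-weighted across folds), and the per-fold mean sensitivity.
#'
#' @param samples a `pixel_sample` data frame covering >= 2 scenes.
#' @param condition label stored in the summary.
#' @param threshold classification threshold.
#' @return An object of class `discrimination_summary`: `condition`,
#'   `folds` (data frame: scene_id, TP, FN, TN, FP, sensitivity,
#'   specificity, method), `pooled_misclassification`, `mean_sensitivity`,
#'   `n_scenes`.
#' @export
loocv_sensitivity <- function(samples, condition = "", threshold = 0.5) {
  scenes <- unique(samples$scene_id)
  if (length(scenes) < 2L) {
    stop("leave-one-out needs at least 2 scenes", call. = FALSE)
  }
  folds <- lapply(scenes, function(sc) {
    train <- samples[samples$scene_id != sc, , drop = FALSE]
    test <- samples[samples$scene_id == sc, , drop = FALSE]
    model <- fit_binomial_mixed(train)
    pred <- predict_heldout(model, test, threshold = threshold)
    is_t <- pred$class == "target"
    tp <- sum(is_t & pred$label == "target")
    fn <- sum(is_t & pred$label == "background")
    tn <- sum(!is_t & pred$label == "background")
    fp <- sum(!is_t & pred$label == "target")
    data.frame(scene_id = sc, TP = tp, FN = fn, TN = tn, FP = fp,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               method = model$method, stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  structure(list(condition = condition, folds = folds,
                 pooled_misclassification = sum(folds$FN) /
                   sum(folds$TP + folds$FN),
                 mean_sensitivity = mean(folds$sensitivity),
                 n_scenes = length(scenes)),
            class = "discrimination_summary")
}

#' @export
print.discrimination_summary <- function(x, ...) {
  cat(sprintf(
    "<discrimination_summary '%s': %d scenes, pooled misclassification %.3f, mean sensitivity %.3f>\n",
    x$condition, x$n_scenes, x$pooled_misclassification, x$mean_sensitivity))
  invisible(x)
}
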