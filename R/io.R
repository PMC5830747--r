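#' Read and write pipeline artefacts
#'
#' Raw scenes interchange as 8/16-bit PNG with a structured-text (YAML)
#' sidecar describing the calibration patches; ground-truth masks as
#' single-channel label PNGs (0 = excluded, 1 = background, 2 = target);
#' linearized, cone-catch and opponent images as 32-bit float multi-channel
#' TIFF; pixel samples and result tables as CSV.
#'
#' @param raw a `raw_image`.
#' @param path output path (`.png`).
#' @return The path, invisibly.
#' @export
write_raw_image <- function(raw, path) {
  stopifnot(inherits(raw, "raw_image"))
  dn_max <- 2^raw$bit_depth - 1
  png::writePNG(raw$dn / dn_max, path)
  meta <- list(scene_id = raw$scene_id, bit_depth = raw$bit_depth,
               patches = lapply(raw$patches, function(p) {
                 list(reflectance = p$reflectance,
                      rows = range(p$rows), cols = range(p$cols),
                      grey_standard = isTRUE(p$grey_standard))
               }))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_raw_image
#' @export
read_raw_image <- function(path) {
  img <- png::readPNG(path)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  dn_max <- 2^meta$bit_depth - 1
  dn <- array(as.integer(round(img * dn_max)), dim = dim(img))
  patches <- lapply(meta$patches, function(p) {
    list(reflectance = p$reflectance,
         rows = seq(p$rows[1], p$rows[2]),
         cols = seq(p$cols[1], p$cols[2]),
         grey_standard = isTRUE(p$grey_standard))
  })
  structure(list(dn = dn, patches = patches, bit_depth = meta$bit_depth,
                 scene_id = meta$scene_id),
            class = "raw_image")
}

#' @rdname write_raw_image
#' @param truth a `scene_truth`.
#' @export
write_truth_masks <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  lab <- matrix(0, nrow(truth$target), ncol(truth$target))
  lab[truth$background] <- 1
  lab[truth$target] <- 2
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' @rdname write_raw_image
#' @param image a `linear_image`, `cone_catch_image` or `opponent_image`.
#' @export
write_float_image <- function(image, path) {
  arr <- if (inherits(image, "linear_image")) image$linear
  else if (inherits(image, "cone_catch_image")) image$catch
  else if (inherits(image, "opponent_image")) image$channels
  else stop("unsupported image class")
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

# write all tabular outputs of an experiment run, with provenance
write_experiment <- function(x, out_dir) {
  stopifnot(inherits(x, "stripeblend_experiment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- x$config
  prov <- list(
    seed = cfg$seed,
    n_scenes = cfg$n_scenes,
    conditions = cfg$conditions,
    n_pixels = cfg$n_pixels,
    scene = cfg$scene[setdiff(names(cfg$scene), "target_center")],
    camera = list(gamma = cfg$camera$gamma, gain = cfg$camera$gain,
                  noise_sd = cfg$camera$noise_sd,
                  bit_depth = cfg$camera$bit_depth))
  chars <- utf8ToInt(paste(deparse(prov), collapse = ""))
  prov$config_hash <- sprintf("%08x",
                              sum(chars * seq_along(chars)) %% 2^31)
  yaml::write_yaml(prov, file.path(out_dir, "config.yml"))
  utils::write.csv(x$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(x$separation, file.path(out_dir, "separation.csv"),
                   row.names = FALSE)
  for (cond in names(x$summaries)) {
    utils::write.csv(x$summaries[[cond]]$folds,
                     file.path(out_dir, sprintf("folds_%s.csv", cond)),
                     row.names = FALSE)
    utils::write.csv(
      x$samples[[cond]][, c("scene_id", "class", "L", "RG", "YB")],
      file.path(out_dir, sprintf("pixels_%s.csv", cond)),
      row.names = FALSE)
  }
  invisible(out_dir)
}
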