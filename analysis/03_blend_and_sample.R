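#!/usr/bin/env Rscript
# Stage 3: viewing conditions and pixel sampling.
#
# For each scene: linearize, map to cone catches, then apply the three
# viewing conditions — high (native resolution), low (Gaussian blend,
# sigma = half a target length), average (per-region mean colour) —
# compute the opponent channels (luminance, red-green, yellow-blue) and
# sample up to 1000 pixels per class without replacement. Under the low
# condition, pixels within 4 sigma of the calibration strip are dropped so
# patch colours cannot leak into the samples. CSVs to results/pixels_*.csv.

library(stripeblend)

seed <- 1L
dir.create("results", showWarnings = FALSE)

config <- experiment_config(seed = seed)
seeds <- stripeblend:::derive_seeds(config$seed, 3L)
scenes <- make_scene_set(config$scene, config$n_scenes,
                         base_seed = seeds[1], camera = config$camera)
map <- fit_rgb_to_cone_map(
  scene_training_spectra(config$n_training_spectra, seed = seeds[2]),
  config$camera, config$receptors, config$illuminant, seed = seeds[2])

catches <- lapply(scenes, function(sc) {
  pd <- extract_patch_dn(sc$raw)
  lmod <- fit_linearization(pd$dn_means, pd$reflectances,
                            dn_max = config$camera$dn_max)
  apply_map(linearize(sc$raw, lmod, ppl = sc$truth$ppl), map)
})

sample_seeds <- matrix(
  stripeblend:::derive_seeds(seeds[3], config$n_scenes * 3L),
  nrow = config$n_scenes, dimnames = list(NULL, c("high", "low", "average")))

for (cond in c("high", "low", "average")) {
  samp <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    truth <- scenes[[i]]$truth
    img <- apply_condition(catches[[i]], truth, viewing_condition(cond))
    opp <- opponent_channels(img)
    margin <- if (cond == "low") ceiling(4 * img$sigma_px) else 0L
    sample_pixels(opp, truth, n_max = config$n_pixels,
                  seed = sample_seeds[i, cond],
                  exclusion_margin_px = margin)
  }))
  write.csv(samp[, c("scene_id", "class", "L", "RG", "YB")],
            sprintf("results/pixels_%s.csv", cond), row.names = FALSE)
  cat(sprintf("condition %-7s: %5d pixels (%d target, %d background)\n",
              cond, nrow(samp), sum(samp$class == "target"),
              sum(samp$class == "background")))
}
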