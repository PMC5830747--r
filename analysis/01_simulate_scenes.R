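#!/usr/bin/env Rscript
# Stage 1: render the synthetic scene set.
#
# Ten "photographs" of an orange-and-black striped elliptical target on a
# background whose spectrum equals the duty-cycle-weighted mean of the
# stripe colours (the fully mean-matched case), each with an embedded strip
# of flat calibration patches including the 15% grey standard. Geometry
# (target size, position, stripe phase) is jittered per scene. Images and
# ground-truth masks go to results/scenes/.

library(stripeblend)

seed <- 1L
out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- experiment_config(seed = seed)
seeds <- stripeblend:::derive_seeds(config$seed, 3L)
scenes <- make_scene_set(config$scene, config$n_scenes,
                         base_seed = seeds[1], camera = config$camera)

for (sc in scenes) {
  id <- sc$truth$scene_id
  write_raw_image(sc$raw, file.path(out, paste0(id, ".png")))
  write_truth_masks(sc$truth, file.path(out, paste0(id, "_mask.png")))
}

areas <- vapply(scenes, function(s) sum(s$truth$target), integer(1))
cat(sprintf("rendered %d scenes to %s\n", length(scenes), out))
cat(sprintf("target areas: %s px (sampling budget 1000/class)\n",
            paste(areas, collapse = ", ")))
cat(sprintf("pixels per target length: %s\n",
            paste(round(vapply(scenes, function(s) s$truth$ppl, numeric(1))),
                  collapse = ", ")))
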