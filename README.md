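# stripeblend

Quantifying distance-dependent conspicuousness of striped prey through
avian eyes.

## The problem

Many chemically defended insects advertise themselves with high-contrast
warning patterns — the orange-and-black striped caterpillar on a green stem
is the canonical case. A predator's visual acuity is finite, so from far
enough away adjacent stripes can no longer be resolved and their colours
fuse into their spatial mean ("pattern blending"). If that blended mean
colour resembles the background, one and the same pattern can be a salient
warning signal at close range and camouflage at a distance.

`stripeblend` implements a complete, testable pipeline for measuring this
effect without requiring field photographs: it *simulates* calibrated
photographs of a striped target with known ground truth, and then treats
them exactly as a field workflow would treat real images:

1. **Scene synthesis** (`render_scene`, `make_scene_set`) — an elliptical
   striped target (stripe reflectances: long-pass "orange", flat "black")
   on a stem-like background, rendered through a camera model with a gamma
   tone curve and sensor noise, with embedded flat calibration patches
   including a 15% grey standard. The background spectrum can be set to
   the duty-cycle-weighted mean of the stripe colours (the fully
   mean-matched case) or displaced from it.
2. **Calibration** (`fit_linearization`, `linearize`) — recover the
   per-channel power-law tone curve from the patches, invert it, and
   anchor reflectance units on the grey standard.
3. **Avian vision** (`receptor_sensitivity`, `fit_rgb_to_cone_map`,
   `apply_map`, `opponent_channels`) — starling-like receptor set built
   from a vitamin-A1 pigment nomogram with oil-droplet cut-offs and
   ocular-media filtering (single cones LWS 563, MWS 504, SWS 449,
   UVS 362 nm; double cone D 563 nm for luminance). Per-pixel cone catches
   are predicted from the calibrated camera channels by a least-squares
   map, then collapsed into an opponent colour space:

       L  = Q_D
       RG = (Q_L − Q_M) / (Q_L + Q_M)
       YB = (Q_L + Q_M − Q_S) / (Q_L + Q_M + Q_S)

   UV information is modelled but deliberately excluded from the analysis
   space (negligible for stems and caterpillar-like targets).
4. **Acuity** (`gaussian_blend`, `apply_condition`, `sample_pixels`) —
   viewing distance is represented by Gaussian pattern blending of the
   cone-catch image. Three conditions: `high` (native resolution), `low`
   (sigma = half a target length, beyond the stripes' resolution limit)
   and `average` (each region replaced by its mean colour). Up to 1000
   pixels per class per scene are sampled without replacement.
5. **Discrimination** (`fit_binomial_mixed`, `loocv_sensitivity`) — a
   binomial mixed model (fixed effects: standardized L, RG, YB; random
   intercept per scene) classifies pixels as target vs background under
   leave-one-scene-out cross-validation, reporting per-fold sensitivity
   and the pooled misclassification of target pixels.

`run_experiment()` orchestrates all of it deterministically from one seed.

## Worked example

```r
library(stripeblend)
ex <- run_experiment(experiment_config(seed = 1), verbose = FALSE)
print(ex)
```

```
Distance-dependent discriminability experiment
  10 scenes, conditions: high, low, average
  condition n_scenes pooled_misclassification mean_sensitivity     sep_L    sep_RG    sep_YB
1      high       10                 0.000705           0.9993 2.895e-04 0.1878071 1.454e-01
2       low       10                 0.568738           0.4338 4.340e-06 0.0001430 4.734e-06
3   average       10                 0.402860           0.6000 9.294e-05 0.0002342 1.109e-04
```

Reading the table: at close range (`high`) almost no target pixel is
mistaken for background — the striped target is conspicuous, with a large
red-green separation (0.188) because the *pixel-level* stripe colours sit
far from the background colour in opponent space even though their mean
matches it. Once the pattern blends (`low`, `average`), the per-channel
separations collapse by three orders of magnitude and misclassification
rises to chance-like levels: the fully mean-matched target is
indistinguishable from its background. With the background exactly equal
to the mean stripe colour, `low` and `average` both sit at the
no-information point, so which of the two is worse varies from seed to
seed; displacing the background (`scene_config(delta = ...)`) moves both
away from chance.

The same analysis can be run stage by stage as a scripted workflow:

```sh
Rscript analysis/01_simulate_scenes.R    # scenes + masks -> results/scenes/
Rscript analysis/02_calibrate_and_map.R  # calibration diagnostics
Rscript analysis/03_blend_and_sample.R   # per-condition pixel samples
Rscript analysis/04_discriminate.R       # LOOCV results + figure
```

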