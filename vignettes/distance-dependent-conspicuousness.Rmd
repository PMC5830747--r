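---
title: "Methods: distance-dependent conspicuousness of striped prey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-dependent conspicuousness of striped prey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

A high-contrast striped pattern — orange and black rings on a caterpillar,
say — is salient at close range. A viewer with finite visual acuity,
however, cannot resolve the stripes beyond some distance: adjacent colour
patches fuse into their spatial mean. If that mean colour matches the
background, the very pattern that advertises the animal up close hides it
from afar. `stripeblend` measures this trade-off as a function of
*effective* viewing distance, deliberately without committing to a metric
distance: acuity depends on light level and viewer, so distance is
represented operationally by the amount of spatial blending.

The measurement is a classification question: given the colour of a single
pixel (as a bird-like visual system encodes it), can target pixels be told
apart from background pixels? The pipeline answers it three times — at
native resolution (`high`), after Gaussian blending with a standard
deviation of half a target length (`low`, beyond the resolution limit of
the stripes but not of the target), and with each region collapsed to its
mean colour (`average`, the limiting case of complete blending).

## Synthetic scenes as the experimental substrate

Field photographs come with unknown ground truth; synthetic scenes invert
that. `render_scene()` draws an elliptical target (default 70 x 19 px,
jittered ±10% in length across scenes) whose stripes run perpendicular to
the long axis with period 10 px and duty cycle 0.5, on a background that
by default *equals the duty-cycle-weighted mean of the two stripe
spectra* (`delta = 0`); `delta` displaces the background spectrum
uniformly in reflectance, making the mean match imperfect on demand. The
per-pixel background intensity jitters multiplicatively (sd 0.08),
emulating natural stem heterogeneity — its spectral *shape* is uniform, a
simplification of real stems. The stripe spectra are parametric:
a long-pass sigmoid (inflection 580 nm, 0.05 to 0.60) for orange — the
classic shape of carotenoid-like integument colours — and a flat 5%
reflectance for black; a Gaussian-peak green (550 nm) is available as an
explicit stem spectrum.

Scene sizes were chosen so a target covers about 1040 px: the pixel
sampler takes up to 1000 pixels per class without replacement, and with
±10% size jitter the smallest targets dip slightly under the budget while
most scenes fill it, so the two classes are (nearly) balanced in every
training fold. This matters: with a strongly unbalanced class and
near-null features, the fitted intercept alone drives all predictions to
the majority class.

The camera is a plain trichromat: Gaussian channel sensitivities peaking
at 600/540/460 nm — deliberately *not* the bird's receptors, so the
camera-to-cone mapping is a genuine inference step — a power-law tone
curve (`DN = gain * catch^(1/gamma)`, defaults gamma 2.2, gain 255,
8-bit) and additive sensor noise (sd 2 DN). Calibration patches (flat
reflectances 0.04–0.85, including the 15% grey standard) render noiseless
by default so that calibration is a property of the scene, not of
averaging; patch noise is switchable for robustness checks.

## Calibration

`fit_linearization()` recovers per-channel `(gain, gamma)` by least
squares on `log DN ~ log r` over at least three patches, refusing
non-monotone patch data and fits whose residual RMS exceeds a bound. The
inverse map plus a von-Kries-style per-channel rescaling to the grey
standard (0.15 by construction) produces reflectance-scaled linear
images; saturated pixels are flagged and never sampled. On unquantized
digital numbers the recovery is exact to rounding error; through the
8-bit render it is good to ~0.3% in gamma, which the grey-standard anchor
absorbs.

## The avian observer

Receptor sensitivities are built from a vitamin-A1 pigment template
(Govardovskii-style alpha band) at the starling's peak wavelengths —
LWS 563, MWS 504, SWS 449, UVS 362 nm, double cone D 563 nm — multiplied
by sigmoidal long-pass oil-droplet cut-offs (LWS 570, MWS 505, SWS 445 nm;
none on UVS or D — whether the double cone's droplet should filter
luminance is genuinely open, and "no droplet" is the default here) and an
ocular-media transmission rising at ~323 nm. A Gaussian template is
available as a documented fallback, and tabulated sensitivities can be
supplied in place of templates. Catches are reflectance-referenced,

\[ Q = \frac{\int R(\lambda) I(\lambda) S(\lambda)\,d\lambda}
           {\int I(\lambda) S(\lambda)\,d\lambda}, \]

so a flat reflector yields its reflectance in every receptor and the
(default, equal-energy) illuminant cancels for flat spectra.

How to get cone catches from three camera channels is the one step with
no canonical answer: the package fits, per receptor, a least-squares
polynomial map from noiseless linear camera responses to true
spectrally-computed catches, with held-out R-squared recorded per
receptor. Two choices deserve flagging:

* **Quadratic, not affine, by default.** An affine map passes generic
  R-squared screens (>= 0.95) yet misses the scene's small SWS catches by
  tens of percent, because the SWS band is not an affine functional of
  these three camera channels. The full quadratic brings all scene-point
  errors under a few percent; `degree = 1` restores the affine map.
* **Training spectra stay inside the scene gamut.**
  `scene_training_spectra()` draws flat greys and convex mixtures of the
  scene's stripe/stem spectra. Three channels underdetermine four catches
  for arbitrary reflectances, so out-of-family training spectra buy
  nothing and drag the fit away from the spectra the map will actually
  see. The flip side is a real limitation: applied to spectra far outside
  the calibrated family, the map's errors are unbounded by the reported
  R-squared.

Opponent coding follows the familiar luminance / red–green / yellow–blue
logic, with normalized differences so both chromatic channels are bounded
in [-1, 1] and invariant to overall intensity:
`L = Q_D`, `RG = (Q_L - Q_M)/(Q_L + Q_M)`,
`YB = (Q_L + Q_M - Q_S)/(Q_L + Q_M + Q_S)`. Denominators are floored at
1e-9; all-zero pixels are flagged invalid. No claim is made that birds
possess exactly these channels — they are efficient, bounded descriptors
of the colour space. UV catches are computable from spectra but excluded
from the analysis space, matching the negligible UV content of this kind
of scene; the sampled feature set is structurally `L, RG, YB` only.

## Acuity as Gaussian blending

`gaussian_blend()` convolves each cone-catch channel with an isotropic 2D
Gaussian, kernel truncated at 4 sigma, with half-sample symmetric
(edge-repeating) boundary reflection. Reflection is a deliberate choice
the underlying workflow leaves open: zero padding would darken region
means near edges and bias the comparison. With a symmetric kernel this
boundary preserves the global mean exactly, and the implementation is
separable, linear and matches a brute-force double-sum oracle to 1e-10.

Blur is applied to *cone catches*, and opponent channels are computed
afterwards — optical and retinal blur physically precede opponency. The
`low` condition's sigma is `0.5 * pixels-per-target-length`, with target
length defined as the ellipse major axis. Under `low`, pixels within
4 sigma (chessboard distance) of the excluded calibration strip are
dropped from sampling so patch colours cannot leak into the analysis.
The `average` condition replaces each region with its per-channel,
*per-image* mean — per image rather than pooled across images, matching
the per-scene grouping of the classifier.

## Discrimination

Pixels are classified by a binomial mixed model: response target vs
background, fixed effects the standardized opponent features, random
intercept per scene, Laplace-approximate ML via `lme4::glmer`.
Standardization uses training folds only. Cross-validation leaves one
*scene* out — the scene (one animal per photograph) is the exchangeable
unit — and predicts the held-out scene at population level (its random
intercept, never estimated, is set to zero), thresholding at p > 0.5 (the
canonical, config-exposed choice). Two recorded fallbacks keep degenerate
folds honest: variance collapse to ~0 refits as plain logistic
regression; (quasi-)separation — diverging coefficients or saturated
fitted probabilities — refits with a small ridge penalty
(`glmnet`, alpha 0). Identical feature rows are aggregated into weighted
binomial observations first, which is likelihood-equivalent and makes the
`average` condition (18 distinct rows) fast and stable.

Misclassification of target pixels is reported pooled over folds
(`sum(FN)/sum(TP + FN)`); the per-fold mean sensitivity is emitted
alongside, since either could be the summary a study reports.

## What the defaults show — and what they cannot

With the default fully mean-matched background (`delta = 0`):

* `high` misclassification is ~0.1%: pixel-level stripe colours sit far
  from the background in opponent space even though their *mean* matches
  it — the normalized-difference channels are nonlinear in the catches,
  so a bimodal mixture and its mean are distinct. The striped target is
  conspicuous up close.
* Both blended conditions collapse to chance-like misclassification
  (40–60%), and the per-channel mean separations fall by about three
  orders of magnitude — pattern blending converts the same target into a
  background match.
* Which of `low` and `average` is *worse* is not determined at
  `delta = 0`: with the background exactly equal to the blended mean,
  both conditions retain only per-scene stripe-quantization offsets of
  random sign, their expected misclassification is 0.5, and their
  ordering flips between seeds (verified across base seeds). An imperfect
  mean match (`delta != 0`) is what pins a reproducible ordering; real
  scenes are always in that regime.
* A related caveat applies to *standardized* mean differences: heavy
  blending shrinks within-class variance faster than it shrinks the mean
  separation, so Cohen's-d-style measures can grow under blur even as the
  raw separation vanishes. The separation report emits both; the raw
  per-channel mean separation is the quantity pattern blending drives to
  zero, and the one asserted in the tests.

## Numerical and design notes

* Wavelength grid 300–700 nm at 1 nm, trapezoidal integration.
* All randomness (scene seeds, jitters, sampling, training-spectrum
  draws, train/holdout splits) derives from one base seed;
  `run_experiment()` is bit-reproducible.
* Degenerate inputs: empty masks, missing classes in a training scene,
  non-monotone calibration data, rank-deficient training spectra and
  unknown condition labels all raise informative errors rather than
  propagating silently.
* Problem sizes used throughout the packaged analyses: 10 scenes of
  256 x 240 px, up to 1000 pixels per class per scene, 200 training
  spectra; the test suite exercises the same code on smaller scenes.

## Known limitations

* The scene model is statistical, not photorealistic: no 3D shading,
  illumination gradients, specularities, or spatially structured
  background spectra. Passing tests demonstrate the pipeline's
  correctness on scenes with these statistics, not performance on real
  photographs.
* The camera-to-cone map is only trustworthy on the gamut it was trained
  on (see above).
* Receptor curves are templates, not measured data; they reproduce peak
  wavelengths and realistic shapes, not any individual species' exact
  sensitivities.
* No receptor-noise (just-noticeable-difference) modelling: the analysis
  asks whether colours *differ statistically*, not whether a bird could
  discriminate them at threshold.
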