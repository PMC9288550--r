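---
title: "Facial colour characteristics and preference modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial colour characteristics and preference modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facecolr)
```

## The problem

Human observers judge attractiveness, healthiness and age partly from the
colour of facial skin: its overall lightness and hue, how uniform it is, and
how strongly the eyes, eyebrows and mouth stand out against the surrounding
skin. `facecolr` quantifies these cues as nineteen colour characteristics
per face, computed in CIELAB from calibrated images with explicit region
label maps, and relates them to per-face preference scores through
zero-order correlations, repeated cross-validated class-comparison
regressions, and a penalised importance model.

Because calibrated face-image databases with ratings are not freely
redistributable, the package ships a synthetic cohort generator with known
ground truth. Every downstream stage is exercised and tested against that
ground truth; nothing in the package depends on proprietary data.

## The nineteen characteristics

All computation happens in CIELAB (D65 white point, 2° observer), chosen
for its approximate perceptual uniformity. The characteristics fall into
three classes:

1. **Average/local skin colour** — the mean L\*, a\*, b\* over facial skin
   (the whole face excluding mouth, nose, eyes and brows), plus cheek
   redness (mean a\* over the cheeks) and periorbital lightness (mean L\*
   around the eyes).
2. **Skin colour variation** — the mean colour difference from the mean
   (MCDM) of a region:
   \[
   \mathrm{MCDM} = \frac{1}{N}\sum_{i=1}^{N}
     \sqrt{(L_i^*-\bar L^*)^2 + (a_i^*-\bar a^*)^2 + (b_i^*-\bar b^*)^2}.
   \]
   The whole-face value is the unweighted grand mean of the MCDM of
   forehead, cheeks, nose and chin — deliberately *not* a pooled-pixel
   MCDM, so that between-region mean differences do not masquerade as
   within-region mottle. Cheek MCDM is reported separately.
3. **Facial colour contrast** — for each of eyes, brows and mouth, the
   adapted Michelson contrast per channel,
   \(C = |(A_{\mathrm{skin}}-A_{\mathrm{feature}})/(A_{\mathrm{skin}}+A_{\mathrm{feature}})|\),
   computed on region means against an explicit surround region, plus the
   CIE76 colour difference ΔE between the two mean colours.

Colour difference is plain CIE76 Euclidean distance throughout, not
CIEDE2000: the uniformity and contrast statistics are defined in terms of
the Euclidean metric, and its isometry properties (rotation invariance,
exact scaling) are part of the test contract.

### Numerical and degenerate-input policy

* Region means and MCDM are computed in double precision on floating-point
  Lab values; images read from 8/16-bit files are scaled to `[0, 1]` before
  conversion so quantisation never enters the statistics at more than
  ΔE ≈ 0.3 per pixel.
* Michelson contrast on a\* and b\* can in principle hit a near-zero
  denominator (both axes are signed). Below `|skin + feature| < 1e-6` the
  package raises a typed degenerate-contrast error naming the channel
  rather than returning an unbounded value that would silently poison the
  regressions. Natural face colours are nowhere near this regime.
* Empty regions raise errors naming the region; feature extraction wraps
  them with the face identifier.
* `lab_to_srgb()` treats out-of-gamut pixels per policy: `clip` (default,
  with a warning and a clipped-pixel count) or `error`.

### Why the surround is an explicit label

The surround of each feature is an explicit region label in the mask, not a
morphological dilation performed at extraction time. Manual, image-specific
area selection is the norm for this kind of colorimetric work; explicit
labels keep extraction deterministic and let masks be audited as data. A
dilation helper (`add_surround()`, Chebyshev radius, default 6 px) is
provided for *building* masks, including the generator's.

Two further choices the definitions leave open: the contrast formula uses
plain means of the full feature region (no trimming), and the average
facial colour pools every skin-type label (facial skin, forehead, cheeks,
chin, periorbital, surrounds) while excluding nose, eyes, brows and mouth.

## The synthetic cohort generator

`generate_face()` paints a schematic face — an ellipse on an exact mid-grey
background (L\*, a\*, b\* = 50, 0, 0) with rectangular/elliptical regions
for the four skin areas, periorbital bands, three features, and a 6-px
surround ring per feature — at configured mean colours plus isotropic
Gaussian Lab noise. For i.i.d. noise with per-channel SD σ the distance of
a pixel from the region mean is σ times a χ(3) variate, so
E[MCDM] = σ·√(8/π); the generator inverts this so that a requested target
MCDM is hit in expectation. The calibration constant is itself verified by
Monte Carlo in the acceptance tests, and extracted MCDM on ~10⁴-pixel
regions is required to sit within three standard errors of targets 0.5–4.

`cohort_spec()` draws per-face parameters independently from truncated
normals. The defaults — skin means near (66, 12, 14) and (62, 13, 17) for
the two cohorts with SDs (3, 1.2, 1.5), MCDM levels around 2 CIELAB units,
dark features around L\* 30–35 and a reddish mouth — are fixed
configuration chosen to span natural skin gamuts and realistic
within-region variation, and are documented as configuration, not as a
reproduction of any measured population.

`simulate_ratings()` uses a latent-score model: face score = intercept +
Σ β·z(feature) + face noise; each of the 22 observers adds a stable bias
and per-rating noise; ratings are rounded half-up and clamped to the
7-point (attractiveness, healthiness) or 1–99-year (age) scale. With the
default noise levels, observer consistency (Cronbach's α with observers as
items) lands around 0.88–0.98 — deliberately in the "highly consistent"
regime reported for real rating panels. The default betas make both
hedonic attributes depend on skin uniformity, lightness and mouth contrast
with shared structure, which induces a strong attractiveness–healthiness
correlation at the face level.

What the generator does **not** emulate: facial geometry and its
attractiveness cues, spatial correlation of skin texture (noise is i.i.d.
per pixel; MCDM is insensitive to spatial arrangement by design), specular
highlights, and camera characterisation error. Passing tests therefore
demonstrate that the *pipeline* recovers known colour-statistical ground
truth — not that the synthetic faces are photometrically realistic.

## Statistics and models

* Per-face scores are observer means; reliability is Cronbach's α with
  observers as items and faces as cases (sample variances, `n−1`).
* Correlations are two-tailed Pearson, with p from the exact t
  transformation on n−2 df. Significance stars at 0.05/0.01/0.001 are
  applied on exact p-values with **no** multiple-testing correction —
  matching how such correlation panels are conventionally reported — and
  the report records the number of tests performed.
* Between-cohort differences use Welch's unequal-variance t-test; at equal
  group sizes of ~40 the difference from the pooled test is negligible,
  and Welch is the safer default.
* All predictors are z-standardised (sample SD). Inside cross-validation,
  scaling uses training-split statistics applied to the held-out fold, so
  no information leaks from test to train; a `scaling = "whole"` switch
  reproduces one-shot whole-dataset standardisation for comparison.

### Class comparison

`separate_class_models()` fits OLS on each class's predictors alone under
5-fold × 50-repeat cross-validation (250 random splits, fold sizes within
one of equal) and reports the mean and SD of per-split test RMSE. The
contrast-class model uses all **12** contrast features including the ΔE
contrasts. Rank-deficient training designs fall back to the minimum-norm
SVD solution with a warning rather than dropping columns, keeping the
per-split coefficient dimension stable.

### Combined importance model

`combined_model()` enters **16** predictors — the nineteen minus the three
ΔE contrasts, which are near-collinear with one of their channel
contrasts — into one elastic net:

\[
\min_{\mu,\beta}\; \frac{1}{2n}\sum_i (y_i-\mu-x_i^\top\beta)^2
 + \lambda\Big(\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2
 + \alpha\lVert\beta\rVert_1\Big),
\]

with α the L1 mixing fraction and λ the overall strength (the dominant
parametrisation; the tuned optimum is invariant to how the two knobs are
labelled). The solver is covariance-form coordinate descent written for
this package, warm-started along the λ path; at λ = 0 it reproduces
closed-form OLS to 1e-6 and at α = 1, λ ≥ max|X'y|/n it returns the exact
null model — both are acceptance anchors, and an installed general-purpose
penalised-regression library is used in the test suite purely as an
independent cross-check on the attained objective value.

Hyperparameters are tuned **once** over the full grid
(α ∈ {0, 0.1, …, 1}; λ: 50 log-spaced values in [1e-4, 10], spanning
near-OLS to all-zero on z-scored predictors) by mean test RMSE over the
same 250 splits, with ties broken toward larger λ then larger α (the
sparser model). The model is then refit on each of the 250 training splits
at the chosen pair; the report carries the per-split test RMSEs and the
mean signed coefficient \(\bar\beta\) per predictor, ranked by
\(|\bar\beta|\). Whether tuning should be nested inside each repeat is a
genuinely open design question; the global reading is implemented because
it matches the two-stage "first tune, then assess" description this
analysis follows, and nested CV would multiply cost 250-fold for a
selection that is stable across splits at these problem sizes. During grid
tuning the solver runs at a relaxed tolerance (1e-4 on coefficient
updates); final refits use 1e-9. The tolerance split matters only for
speed: grid selection compares RMSE differences orders of magnitude larger
than the fit error.

## Pipeline and reproducibility

`run_pipeline()` runs generate → extract → rate → correlate → model per
cohort, each cohort fully separately (no pooled model), then the
between-cohort Welch tests, and writes CSV/JSON artefacts plus a manifest
with config echo, per-stage wall-clock and MD5 hashes. All randomness
descends from one master seed through fixed arithmetic; the global RNG
state is saved and restored around every seeded computation, so package
calls never perturb a caller's stream. Two runs with the same config and
seed produce byte-identical CSV/JSON outputs (the manifest is excluded
from that guarantee only because it records timings).

## Problem sizes used in the tests

The test-suite and acceptance experiments use deliberately desk-scale
sizes, chosen once as adequate for their statistical purpose: 96–128-px
images for exactness and round-trip checks; 440-px images (≈10⁴-pixel
forehead) × 50 seeds for noise calibration; 100 replicate cohorts of 40
faces for sparse-recovery of the combined model (3 active predictors of 16
at |β| = 0.5 with outcome noise SD 0.5, requiring top-5 rank recovery in
≥ 90% and sign recovery in ≥ 95% of replicates); and 50 replicates for the
class-attribution check (the generating class must achieve the lowest mean
RMSE in ≥ 95%). Cohort-level simulations for the model-recovery
experiments use the generator's ground-truth feature vectors directly,
without rasterising pixels: the models consume per-face feature tables, so
pixel rendering would add cost but no information to those experiments
(the feature-extraction path has its own pixel-level tests).

## Known limitations

* The sRGB→CIELAB path assumes standard sRGB input; images captured under
  a characterised camera model will not numerically match values computed
  from raw device RGB.
* Masks must be supplied (or generated); there is no automatic face
  detection or skin segmentation.
* The generator's rating model is illustrative: real observer panels have
  unknown noise structure, and the default betas are configuration, not
  estimates.
* Class comparison is descriptive — no significance test between class
  RMSE distributions is reported, by design.
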