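# facecolr

Colour cues carried by facial skin — overall lightness and hue, skin
colour uniformity, and how strongly the eyes, eyebrows and mouth contrast
with the surrounding skin — shape how faces are judged for attractiveness,
healthiness and age. `facecolr` is an R package for researchers in colour
science and face perception who want to quantify those cues from
calibrated images and model their link to observer ratings, end to end and
reproducibly.

## What it computes

From a CIELAB image paired with a region label map, the package extracts
**nineteen facial colour characteristics** in three classes:

* **Average/local skin colour** — mean L\*, a\*, b\* over facial skin
  (excluding mouth, nose, eyes, brows), cheek redness (cheek a\*) and
  periorbital lightness (periorbital L\*).
* **Skin colour variation** — the mean colour difference from the mean,

  ```
  MCDM = (1/N) Σᵢ √[(Lᵢ*−L̄*)² + (aᵢ*−ā*)² + (bᵢ*−b̄*)²]
  ```

  for the cheek, and as the grand mean over forehead, cheek, nose and
  chin for the whole face.
* **Facial colour contrast** — per channel, the adapted Michelson contrast
  `C = |(A_skin − A_feature)/(A_skin + A_feature)|` between each of
  eyes/brows/mouth and its surrounding skin, plus the CIE76 colour
  difference ΔE between the two region means.

Downstream, the package provides observer-reliability (Cronbach's α),
two-tailed Pearson correlation panels with significance stars, Welch
between-cohort tests, 5-fold × 50-repeat cross-validated OLS models
comparing the predictive power of the three classes (mean test RMSE over
250 splits), and a combined 16-predictor elastic net

```
(1/2n)·Σ(yᵢ − μ − xᵢ'β)² + λ·[(1−α)/2·‖β‖₂² + α·‖β‖₁]
```

tuned over an (α, λ) grid by cross-validated RMSE, with predictor
importance ranked by the absolute mean signed coefficient |β̄| across the
250 training refits.

A synthetic face-cohort generator (schematic faces with calibrated
Gaussian Lab noise, E[MCDM] = σ√(8/π), plus a latent-score observer
rating model) supplies ground truth for every stage, so the whole pipeline
is testable without access to restricted face-image databases.

## Worked example

```r
library(facecolr)

# generate a synthetic cohort of 40 faces with known ground truth
cohort   <- generate_cohort(cohort_spec(n_faces = 40, seed = 7))
features <- extract_features_cohort(cohort$faces)

# simulate a 22-observer rating panel and average to per-face scores
ratings <- simulate_ratings(features, rating_model(seed = 7))
scores  <- mean_scores(ratings)
cronbach_alpha(dplyr::filter(ratings, attribute == "attractiveness"))
#> [1] 0.91

# zero-order correlations of each characteristic with each preference
cm <- correlation_matrix(features, scores)
dplyr::filter(cm, feature == "MCDM")
#>   feature attribute           r        p     n stars
#> 1 MCDM    age             0.557 0.000189    40 ***
#> 2 MCDM    attractiveness -0.551 0.000232    40 ***
#> 3 MCDM    healthiness    -0.534 0.000390    40 ***

# which class of characteristics predicts attractiveness best?
cc <- separate_class_models(features, scores, cv_config(seed = 7))
tidy(cc)
#>   attribute      class         mean_rmse sd_rmse n_splits
#> 1 attractiveness average_local     0.693   0.208      250
#> 2 attractiveness contrast          0.852   0.227      250
#> 3 attractiveness variation         0.516   0.137      250

# combined elastic-net importance model (16 predictors)
combined_model(features, scores, "attractiveness", cv_config(seed = 7))
#> Combined elastic-net model for 'attractiveness' (n = 40 faces, 250 splits)
#>   alpha = 0.90, lambda = 0.0569
#>   mean RMSE = 0.425 (SD 0.107)
#>   top predictors by |mean beta|:
#>      1. MCDM           -0.316
#>      2. MCDM_cheek     -0.246
#>      3. mouth_C_a      +0.184
#>      4. periorbital_L  +0.090
#>      5. L              +0.054
```

Read this as: observers in this simulated panel agree strongly (α = 0.91);
less uniform skin (higher MCDM) is associated with older, less attractive,
less healthy-looking faces (r ≈ ±0.55); of the three classes, skin colour
variation alone predicts attractiveness best (mean held-out RMSE 0.52
points on the 7-point scale); and the combined model predicts
attractiveness within 0.43 points, driven mainly by the two skin-variation
measures and mouth redness contrast — matching the betas the rating
simulator was configured with.

`run_pipeline(default_run_config(seed = 1))` runs the whole two-cohort
analysis (generation, extraction, ratings, correlations, class models,
combined models, Welch between-cohort tests) and writes CSV/JSON artefacts
plus a manifest; `render_report()` turns a run directory into a markdown
summary. A thin CLI over the same functions lives at
`inst/cli/facecolr.R` (verbs `generate`, `extract`, `analyze`, `run`,
`report`). The methods vignette
(`vignettes/facial-colour-preference.Rmd`) documents the statistical
choices, generator calibration and limitations.

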