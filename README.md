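# droptex

Texture analysis of dried-droplet deposit micrographs.

When a droplet of a protein–salt solution evaporates on a surface it leaves
a structured deposit: a coffee ring at the pinned contact line, and —
depending on salt concentration, relative protein concentration and
humidity — dendrites, needles, rosettes and star-like crystals inside it.
These patterns are increasingly used as cheap diagnostic readouts of
biofluid composition, which requires *quantitative* descriptors of deposit
texture rather than visual inspection. `droptex` provides that pipeline for
anyone analyzing micrographs of drying-droplet deposits: image-analysis
researchers, soft-matter experimentalists, and developers of drop-based
diagnostic assays.

## What it computes

**The ten-parameter texture descriptor.** From an 8-bit grayscale
micrograph with gray levels g ∈ {0, …, N_g−1} and histogram
H(g) = n_g / N:

* First-order statistics (FOS): mean μ = Σ g·H(g); standard deviation
  σ = √Σ (g−μ)²H(g); integrated density I = μ·N; skewness
  μ₃ = Σ(g−μ)³H(g)/σ³; excess kurtosis μ₄ = Σ(g−μ)⁴H(g)/σ⁴ − 3.
  These are population moments of the histogram; σ = 0 (constant image)
  makes the shape moments undefined and they are reported as `NA`.
* Gray-level co-occurrence (GLCM) features from the normalized
  co-occurrence matrix p(i,j) at displacement distance d = 3, averaged
  over the four canonical angles (0°, 45°, 90°, 135°): energy Σp²,
  inertia (contrast) Σ(i−j)²p, correlation (Σij·p − μxμy)/(σxσy),
  inverse difference moment Σp/(1+(i−j)²), and entropy −Σp·log p.

**The saturating exponential response law.** Texture parameters measured
across a salt-concentration series φ follow

δ(φ) = −δ₀·e^(−φ/k) + δ_s

where δ_s is the saturation value, δ_s − δ₀ the bare-surface value at
φ = 0, and k the characteristic concentration at which the gap to
saturation has shrunk by 1/e. `fit_texture_law()` estimates (δ₀, k, δ_s)
by nonlinear least squares (k kept positive via log-parameterization) and
returns a model object with `coef`, `predict`, `residuals`, `summary`,
`simulate` and `plot` methods.

**Canonical discriminant classification.** `fit_cda()` solves the
between-group versus pooled within-group scatter eigenproblem, reports
unstandardized canonical coefficients, eigenvalues, the sequential Wilks'
Λ chain with Bartlett chi-square tests, group centroids and the training
(resubstitution) confusion table; `classify()` assigns new deposits to the
nearest group centroid in canonical space.

**Formation-stage analysis.** `compute_trajectory()` tracks all ten
parameters across an evaporation frame sequence and `segment_stages()`
finds the three formation stages (coffee-ring formation, crystal growth,
water drying) by exact least-squares change-point detection.

**Synthetic deposits.** Because real micrograph corpora are rarely
shareable, `generate_deposit()`, `generate_series()`,
`generate_evaporation_sequence()` and `generate_feature_table()` create
seeded synthetic images and feature tables with known ground truth
(crystal density, response-law parameters, stage boundaries, group
centroids) so every stage of the pipeline can be validated end to end.

## Worked example

```r
library(droptex)

## a synthetic deposit and its descriptor
img <- generate_deposit(deposit_spec(crystal_density = 0.008, seed = 7))
compute_fos(img)
#>               mean                std integrated_density           skewness
#>          6.967e+01          7.066e+01          6.421e+05          1.244e+00
#>    kurtosis_excess
#>          1.774e-01
glcm_features_protocol(img)
#>      energy     inertia correlation         idm     entropy
#>   1.353e-03   5.935e+03   4.131e-01   1.513e-01   7.242e+00
```

The image mean is ≈ 70 gray levels with strong right skew (bright
crystals on a darker disc); the low energy (≈ 0.0014) and high entropy
(≈ 7.2 nats) say the co-occurrence mass is spread over many gray-level
pairs — a heterogeneous, crystal-rich texture.

```r
## response of the image mean across a synthetic salt sweep
sp  <- series_spec(seed = 7)            # true k = 0.25
ser <- generate_series(sp)
m   <- sapply(ser$images, function(i) compute_fos(i)$mean)
agg <- aggregate(m ~ ser$manifest$condition, data.frame(m), mean)
fit_texture_law(condition_series(agg[[1]], agg[[2]]))
#> Saturating exponential texture-response law
#>   delta(x) = -delta0 * exp(-x/k) + delta_s
#>  delta0       k delta_s
#>  9.6832  0.2555 71.1090
#> rss = 0.193987, R^2 = 0.9975, converged
```

The fitted characteristic concentration (k ≈ 0.256) recovers the
generator's truth (0.25) within ~2%, through the full image pipeline.

```r
## classifying five deposit groups, 24 replicates each
tab   <- generate_feature_table(g = 5, n_per_group = 24,
                                centroid_separation = 10, seed = 7)
model <- fit_cda(tab$features, tab$labels)
model
#> Canonical discriminant analysis: 5 groups, 10 features, n = 120
#> 4 candidate function(s), 4 retained at alpha = 0.05
#>             eigenvalue wilks_lambda chi_square df    p_value
#> through CF1      32.65    2.679e-06     1431.0 40 3.288e-274
#> ...
error_rate(model, cbind(tab$features, .group = tab$labels))$overall
#> [1] 0
```

Small Wilks' Λ with p ≪ 0.05 says the group means differ strongly; the
resubstitution error of 0 means every training deposit lands in its own
group.

```r
## formation stages of a synthetic evaporation sequence
ev  <- generate_evaporation_sequence()        # true boundaries 8, 16
seg <- segment_stages(compute_trajectory(ev$sequence))
seg$boundaries
#> [1]  8 16
```

A batch command-line front-end over the same functions lives in
`inst/cli/droptex.R` (subcommands `features`, `fit`, `classify`,
`timeseries`, `synth`).

## Further reading

The methods vignette (`vignettes/droptex-methods.Rmd`) documents the
model assumptions, the conventions chosen where the field's practice is
ambiguous (correlation denominator, entropy log base, angle averaging),
the synthetic generator's design and its limits, and known limitations.
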