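---
title: "Methods behind droptex: texture statistics, response laws, and deposit classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind droptex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droptex)
```

# The measurement problem

A drying droplet of a protein–salt solution leaves a deposit whose
morphology encodes its composition: capillary flow builds a coffee ring at
the pinned contact line, and dissolved salt crystallizes into needles,
stars, and dendritic branches whose abundance grows with salt
concentration. `droptex` turns a micrograph of such a deposit into a
ten-number texture descriptor and provides the two statistical models used
to interpret it — a saturating exponential response law across a
concentration series, and canonical discriminant classification of deposit
groups — together with a synthetic image generator that makes the whole
chain testable against known ground truth.

All analysis operates on 8-bit grayscale images: a matrix of integer gray
levels in \([0, N_g-1]\) with \(N_g = 256\) by default. Color input is
reduced by Rec. 709 luminance (0.2126 R + 0.7152 G + 0.0722 B); the
camera-to-gray path of any particular acquisition setup is not modelled,
and any fixed documented convention serves, since all comparisons happen
within one pipeline. No background subtraction or intensity normalization
is applied: the statistics are computed on raw levels, so acquisition
settings must be constant within a study. Coordinates are (row, col) with
the origin at top-left and the row axis pointing down.

# First-order statistics

With histogram \(H(g) = n_g/N\), the five first-order parameters are the
population moments

\[
\mu = \sum_g g H(g), \qquad
\sigma = \sqrt{\textstyle\sum_g (g-\mu)^2 H(g)}, \qquad
I = \mu N,
\]
\[
\mu_3 = \frac{\sum_g (g-\mu)^3 H(g)}{\sigma^3}, \qquad
\mu_4 = \frac{\sum_g (g-\mu)^4 H(g)}{\sigma^4} - 3 .
\]

Three choices deserve note:

* **Population, not sample, moments.** The formulas are weighted sums over
  the histogram with no \(n-1\) correction; the test suite checks the
  histogram route against direct pixel-list moments to \(10^{-9}\).
* **Kurtosis is excess kurtosis** (the \(-3\) term); the output column is
  named `kurtosis_excess` so no reader can mistake the convention.
* **Degenerate images.** A constant image has \(\sigma = 0\); skewness and
  kurtosis are then undefined and reported as `NA`, never as 0 and never
  as an error. Downstream consumers (the discriminant fit, trajectories)
  treat these as missing.

Integrated density is \(\mu\) times the pixel count *of the analyzed
region* — after any region-of-interest crop — and the region's pixel count
travels with the result, because \(I\) is otherwise meaningless across
images of different sizes.

# Co-occurrence features

The co-occurrence matrix at displacement distance \(d\) and angle
\(\phi\) counts ordered pixel pairs \((x, x + \Delta)\) with both ends
inside the image (no padding, one matrix per whole image) and normalizes
to probabilities \(p(i,j)\). The angle-to-offset map, with the row axis
pointing down, is \(0^\circ \to (0, d)\), \(45^\circ \to (-d, d)\),
\(90^\circ \to (-d, 0)\), \(135^\circ \to (-d, -d)\). Pairs are counted
in both directions by default (`symmetric = TRUE`), which makes the
matrix exactly symmetric and the four-angle average direction-complete; a
one-directional mode exists for comparison with single-direction
implementations.

From \(p(i,j)\) and its marginal moments the five features are energy
\(\sum p^2\), inertia \(\sum (i-j)^2 p\), correlation
\((\sum ij\,p - u_x u_y)/(s_x s_y)\), inverse difference moment
\(\sum p/(1+(i-j)^2)\), and entropy \(-\sum p \log p\) (zero cells
contribute zero, the \(p\log p \to 0\) limit).

Two conventions in the literature are genuinely ambiguous, and both are
implemented:

* **Correlation denominator.** Texts often write the marginal "standard
  deviation" but print the second central *sum* (a variance). The default
  (`correlation_mode = "rooted"`) uses the square root — the standard
  Haralick correlation, bounded in \([-1, 1]\); `"literal"` divides by the
  unrooted sums exactly as printed. Both modes are tested; results from
  the two are not comparable with each other.
* **Entropy base.** Natural log by default (nats); `log_base = 2` gives
  bits. All package-internal comparisons are base-consistent.

The acquisition protocol the package mirrors computes the features at
\(d = 3\) for all four angles and averages them so no directional
arrangement on the surface is favored. Averaging happens at the *feature*
level by default. Pooling the four count matrices first
(`average = "matrix"`) differs for correlation and entropy — both
nonlinear in \(p\) — and is available behind a flag; feature-level
averaging was chosen as the default because it treats each direction as a
repeated measurement of the same scalar. Correlation is `NA` when a
marginal spread is zero (constant image), for the same reason as the
first-order shape moments.

# The saturating exponential response law

Across a concentration series \(\varphi\), each texture parameter
\(\delta\) is modelled as

\[ \delta(\varphi) = -\delta_0 e^{-\varphi/k} + \delta_s , \]

a three-parameter saturation curve: \(\delta_s\) the plateau,
\(\delta_s - \delta_0\) the bare-surface value at \(\varphi = 0\), and
\(k\) (condition units) the characteristic concentration at which the gap
has closed by \(1 - 1/e\). Parameters that *decrease* (skewness, energy,
IDM, correlation) fit the same form with \(\delta_0 < 0\); the curve is
monotone with slope sign equal to the sign of \(\delta_0\) everywhere.

Numerical choices:

* **Initialization from the parameters' data meaning:** \(\delta_s\)
  starts at the largest-\(\varphi\) observation, \(\delta_0\) at the gap
  to the \(\varphi = 0\) observation, \(k\) at the median positive
  condition value. These starts are within the basin of attraction for
  every curve shape the model admits, which the noiseless recovery grid
  (relative error \(< 10^{-6}\) across sign combinations) confirms.
* **Positivity of \(k\)** via fitting \(\log k\); \(\delta_0, \delta_s\)
  unconstrained.
* **Weighting.** Unweighted least squares by default — appropriate when
  per-condition means carry similar uncertainty, as in a balanced
  replicate design; `weighted = TRUE` uses inverse-variance weights from
  per-condition standard deviations.
* **Identifiability floor.** Three free parameters need at least four
  conditions; fewer is an error. A flat series leaves \(k\)
  unidentifiable: the optimizer's failure is caught and the degenerate
  saturation-only estimate (\(\delta_0 = 0\), \(\delta_s\) the weighted
  mean) is returned with `converged = FALSE` and the optimizer's message —
  a diagnosable outcome rather than an exception, so batch fits over many
  parameters never abort.
* **Goodness of fit** is reported as RSS and \(R^2\); no significance
  test of the fit is attached.

# Canonical discriminant analysis

For a labelled feature table (any subset of the ten parameters) with
\(g\) groups and \(p\) features, the model solves the generalized
eigenproblem of between-group scatter \(B\) against pooled within-group
scatter \(W\) (the \(n-g\) denominator convention). The
\(s = \min(p, g-1)\) candidate functions are ordered by decreasing
eigenvalue \(\lambda_i\) and scaled so canonical scores have pooled
within-group variance 1. The sequential tests

\[
\Lambda_m = \prod_{i>m} \frac{1}{1+\lambda_i}, \qquad
\chi^2_m = -\big(n - 1 - \tfrac{p+g}{2}\big) \ln \Lambda_m, \qquad
\mathrm{df} = (p-m)(g-1-m)
\]

(Bartlett's approximation) retain the functions whose test falls below
\(\alpha = 0.05\). The full-model \(\Lambda_0\) equals
\(\det W / \det(W+B)\), which the suite verifies to \(10^{-9}\) against a
determinant oracle and against `stats::manova`'s Wilks statistic.

Classification uses equal priors and the nearest group centroid in
canonical space (Euclidean distance) — natural for balanced designs such
as 24 replicates per condition; exact ties break to the lexicographically
smallest label so results are deterministic. When no function is retained
the first function is still used, since a 0-dimensional rule is useless
and this keeps the permutation-null behavior (training error near
\(1 - 1/g\)) intact. The headline error is resubstitution (training)
error; leave-one-out refitting is available as a diagnostic
(`error_rate(..., loo = TRUE)`) but is not the reported surface. Rows
with undefined features are dropped with a warning before fitting;
singular within-group scatter is an error that names the collinear
columns rather than returning garbage coefficients.

The model is invariant to feature rescaling (affine invariance of
\(\Lambda\), p-values and assignments), asserted in the suite.

# Evaporation trajectories and stage segmentation

`compute_trajectory` evaluates all ten parameters per frame; per-frame
failures become `NA` rows with warnings so a single bad frame never aborts
a sequence. Stage boundaries in drying experiments are traditionally drawn
by eye; the package instead uses the simplest defensible objective — exact
least-squares piecewise-constant change-point detection, dynamic
programming over all boundary placements — and records that choice in the
output metadata. The DP is verified against exhaustive enumeration on
short series; ties prefer the earliest boundaries, making the degenerate
constant-series case deterministic. Missing values are excluded from the
objective with index bookkeeping preserved, and segmentation is invariant
to affine rescaling of the series.

The default segmentation series is GLCM entropy: among the ten parameters
it shifts at both stage transitions in the synthetic sequences (crystal
accretion raises it sharply; haze clearance lowers it), whereas
first-order parameters barely distinguish the final water-drying stage —
a limitation of histogram-only statistics that the trajectory output
makes visible per feature rather than hiding.

# What the synthetic generator emulates — and what it does not

`generate_deposit` renders: dark background, deposit disc (radius 0.45 of
the short side), bright coffee-ring annulus (default width 5 px,
intensity 200), crystals placed by a Poisson process over the disc
(rejection sampling for positions; overlaps allowed, as in real
deposits), and additive Gaussian noise clipped to \([0, 255]\) and
quantized — mirroring 8-bit acquisition. Crystal shapes are stylized:
2×2 speckles, 9-px line-segment needles, plus-shaped stars, 18-step
random-walk dendrites, drawn at intensity \(225 \pm 15\). The target is
*controlled texture statistics with known ground truth*, not
photorealism: real deposits have scalloped rings, graded crystal sizes,
and illumination gradients that the generator deliberately omits. Passing
tests therefore demonstrate correctness of the *statistics and models*,
not validated performance on laboratory micrographs.

`series_spec` maps a pseudo-concentration grid through
\(D(x) = D_s - D_0 e^{-x/k_{\mathrm{true}}}\) to crystal density, so the
measured texture response inherits the exponential law; with
\(D_0 = D_s\) the surface at \(x = 0\) is crystal-free. Defaults:
\(k_{\mathrm{true}} = 0.25\) on a 7-point grid spanning \([0, 1]\)
(emulating a 0–1 wt% salt sweep), \(D_s = 0.012\) crystals per disc
pixel (≈ 70 crystals at saturation in a 96×96 image), and 24 replicates
per condition — the replicate count of the balanced laboratory design the
package mirrors, and enough that Poisson sampling noise does not mask the
small signal increments near saturation. The image mean is the default
recovery feature in the end-to-end check because each crystal adds a
near-constant bright area, making the mean nearly linear in crystal count
and thus an unbiased carrier of \(k_{\mathrm{true}}\); entropy and energy
respond monotonically but saturate nonlinearly.

`generate_evaporation_sequence` builds three stages with sharp texture
transitions: the ring brightens over the first two frames (stage 1), a
crystal population accretes cumulatively from a 60% initial reveal
(stage 2), and a bright noisy water haze (offset 30, sd 12 gray levels)
present through stages 1–2 vanishes at the stage-3 entry — residual water
evaporates quickly. The sharp transitions are a design requirement: a
piecewise-constant objective can only localize boundaries that the
feature series actually expresses as level shifts.

# Problem sizes and tolerances

The validation suite uses sizes chosen to make each check sharp yet quick:
100 random images up to 32×32 at \(N_g \le 16\) for the co-occurrence
oracle (agreement to \(10^{-9}\)); 100 random 8-bit images for the
dual-route moment check; 200 Monte-Carlo fits at 5% noise for law
recovery (median within 10% of truth); 500 null replicates at
\(n = 200\)/group for discriminant calibration (rejection rate within
\([0.03, 0.07]\)); the 5-group × 24-replicate separated design for
classification; a 168-image sweep (7 conditions × 24 replicates, 96×96)
for the end-to-end direction and \(k\)-recovery check (within 25%); and
24-frame sequences for stage recovery (±2 frames). `scripts/acceptance.R`
re-runs the same computations from scratch under a caller-provided seed.

# Known limitations

* Whole-image statistics only: no deposit segmentation, registration or
  illumination correction; a region of interest is the user's tool for
  isolating the deposit.
* The descriptor is the fixed ten-parameter set; other Haralick features
  (cluster shade, sum entropy) and multi-distance sweeps are out of scope.
* The response law is a single functional form; no model selection against
  alternatives is attempted.
* The discriminant is linear with equal priors; regularized or kernel
  variants are not provided.
* Stage segmentation assumes piecewise-constant levels in the chosen
  feature; slow drifts within a stage bias the boundaries, and
  detectability per feature is reported, not guaranteed.
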