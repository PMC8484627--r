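---
title: "Contour features and affective judgements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour features and affective judgements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contouraffect)
```

This vignette is the package's own account of its models, the choices
made where the design was genuinely open, and what the validation suites
do and do not establish.

## Contour geometry

A **contour** is an ordered open polyline of fiducial points on a pixel
canvas, image convention: origin top-left, x rightward, y downward.
All orientations are reported in *visual* space — the counter-clockwise
angle from horizontal that an observer would see — so they are computed
from (Δx, −Δy) and reduced modulo 180°, making them invariant to the
direction in which a contour was traced.

**Angularity** at an interior vertex is the absolute turn angle between
the incoming and outgoing segment directions (0–180°) divided by a
length. Which length is not forced by the construct; we use the *mean*
of the two adjacent segment lengths by default because it is symmetric
under contour reversal and yields degrees per pixel, the natural unit
for a discrete curvature magnitude. `min` and `sum` denominators are
available through `vertex_angularities(denominator=)` for sensitivity
analyses. The turn is unsigned: a left and a right bend of equal size
are equally "sharp". Collinear vertices give 0; two-point contours have
no interior vertex and return an empty vector.

The **folded mean orientation** maps each segment orientation
θ ∈ [0°, 180°) to min(θ, 180° − θ) ∈ [0°, 90°], so near-horizontal
directions coincide at 0 and near-vertical at 90, then takes the
pixel-length-weighted mean. Folding before averaging matters: the raw
circular mean of a contour mixing 10° and 170° segments is 0°/90°
ambiguous, while the folded mean correctly calls it near-horizontal.
Length weighting keeps the summary consistent with the pixel-weighted
histograms; an unweighted variant is available.

## Feature histograms

Each drawing yields three 8-bin histograms whose weights are continuous
pixel lengths (contours are continuous polylines, so "number of pixels"
is interpreted as contour length in pixel units):

* **Orientation** — per segment, at the segment's orientation; centers
  0°, 22.5°, …, 157.5°, circular (157.5° wraps toward 0°).
* **Length** — per contour, all of the contour's length at
  log10(total length); centers 1.66, 4.47, 12.02, 32.36, 87.10, 232.42,
  630.96, 1698.24 px.
* **Angularity** — per interior vertex, the two adjacent half-segments'
  length at log10(angularity); centers 1.38, 2.63, 5.13, 9.77, 18.62,
  35.48, 67.61, 131.83 deg/px.

Masses are split between the two neighbouring centers by **triangular
(linear) interpolation** on the binning scale. The assignment rule is a
design choice — nearest-center assignment is available via `mode =
"nearest"` and agrees exactly when values sit on centers — but
interpolation avoids quantization cliffs when a feature value sits
between centers. Length and angularity values at or beyond the extreme
centers are clamped into the end bins.

The length and angularity centers are close to, but not exactly, what
one would recompute by equally spacing log10 over their nominal ranges;
recomputation from first principles is under-determined (the exact
rounding and range conventions behind the printed values are unknown),
so the centers are treated as verbatim constants of the method.

Two rules keep angularity mass exactly conserved: a vertex carries half
of each adjacent segment, so the outer halves of a contour's first and
last segments (and both halves of a two-point contour) belong to no
vertex and are assigned to bin 1, the zero-turn class; and vertices
whose angularity falls below the first center are likewise clamped to
bin 1. With these rules each histogram's total equals the drawing's
total contour length, a property the tests assert to 1e-6 relative on
random drawings.

The regression **feature vector** concatenates Orientation 1–8,
Length 1–7 and Angularity 1–8 (23 entries). Length 8 is dropped because
contours that long are rare in traced drawings and the bin is nearly
empty. An element-wise square root reduces the influence of outlying
pixel masses. Note 23 retained features: the regression handles any
residual collinearity by pivoted elimination rather than by dropping a
fixed extra column, since no principled choice of such a column exists.

## Valence regression

`fit_valence_model()` is ordinary least squares with an intercept,
fitted by pivoted QR (`stats::lm`). Rank-deficient columns are dropped
deterministically and reported by name; duplicated columns therefore
never change fitted values. p-values are two-sided from the t
distribution and are reported raw, without multiple-testing correction,
matching the exploratory character of the analysis. R² equals
1 − SSE/SST; the overall F test uses (df1 = retained predictors,
df2 = n − df1 − 1).

`partial_regression_data()` returns the added-variable pair — residuals
of y on all-but-one predictors against residuals of that predictor on
the rest — whose slope equals the multiple-regression coefficient
(Frisch–Waugh–Lovell); the tests assert the identity numerically at
1e-8.

`subset_analysis()` fits the close and far image classes independently
and reports a per-class error object rather than failing both when one
class is degenerate, because unbalanced class labels are an expected
input condition.

## Stimulus construction

Contours are classified into 24 bins by `classify_contour()`. The
category boundaries are not intrinsic to the factorial design, so the
defaults reuse the feature-histogram geometry rather than inventing new
constants: length split 87.10 px and angularity splits {5.13, 35.48}
deg/px are histogram bin centers near the middle of each log range, and
the orientation band is 22.5°, half the orientation bin spacing on the
folded scale. A contour whose folded mean orientation lies within the
band of 0° is horizontal, within the band of 90° vertical; in between it
is "both" when more than `extreme_fraction = 0.5` of its pixel length
lies within the band of either extreme (a genuinely bimodal
horizontal-plus-vertical contour), else "diagonal". All cut values are
configurable through `bin_thresholds()`.

Placement divides coordinates by 4 (800×600 tracings onto the 200×150
stimulus grid), shifts a protruding contour by the minimal offset that
brings its bounding box inside, and — when the box exceeds the canvas in
either dimension — truncates whole points from the tail end until it
fits. Truncating whole points rather than clipping mid-segment is the
simplest reading of "shortening" a polyline and never creates new
vertices; a contour reduced below two points is skipped and another
drawn. Bin membership is assessed *before* placement; shortening can
drift a contour's realized features, which is visible in the manifest
(realized lengths are recorded per image).

Within one image contours are sampled without replacement — an image
should not contain the same contour twice — while the pool is reused
freely across images; with-replacement sampling within an image is a
defensible alternative the data cannot distinguish, and the without-
replacement choice makes the pool-exhaustion failure mode explicit (an
error naming the bin). Contours are appended until the summed *placed*
length exceeds 1000 px, so every image carries at least 1000 px of
visible contour. Generation is seed-deterministic: equal seed and
configuration give byte-identical manifests and coordinates.

## Choice model

Each four-image trial contributes exactly two observations: the image
chosen most positive (or safest) with outcome 1 and the image chosen
most negative (most threatening) with outcome 0; the two neutral images
are excluded. The model is logistic with the full
Length × Angularity × Orientation factorial as fixed effects and a
Gaussian random intercept per participant, integrated by the Laplace
approximation.

Factors use **sum-to-zero contrasts** (levels ordered alphabetically):
with interactions present, dropping a lower-order term only tests a
meaningful hypothesis under a coding in which the remaining terms are
orthogonal to the dropped one on balanced data, which sum coding
provides. `likelihood_ratio_tests()` implements Type-III-style tests by
removing each effect's model-matrix columns while retaining all others
and referring 2·ΔlogLik to a chi-square with the removed column count as
degrees of freedom (1, 2, 3 for the main effects; 2, 3, 6 for the
two-way interactions; 6 for the three-way).

Fitting is delegated to established mixed-model engines rather than a
bespoke optimizer: `glmmTMB` (Laplace via TMB) by default, `lme4::glmer`
as an alternative. Both maximize the same Laplace-approximate
likelihood; on a full-size session (37,680 observations) they agree on
the log-likelihood and fixed effects to about 1e-5 while glmmTMB is an
order of magnitude faster, which is why it is the default for the
simulation suites. The tests cross-check the engines against each other
and check the zero-variance limit against a plain logistic fit (IRLS),
including the nesting property logLik(GLMM) ≥ logLik(GLM).

The default random structure is a participant intercept only. A
trial-within-participant intercept can be requested
(`random_structure = "participant_trial"`), but with exactly one 1 and
one 0 per trial the trial intercept is weakly identified — the within-
trial contrast carries no information about it — so it is off by
default.

## Synthetic data

The generators define the study conditions the pipeline is validated
under.

**Bin-targeted contours** (`synth_contour()`) are directed random walks
alternating between two base headings. The absolute turn between the
headings, divided by the segment length, sets the per-vertex angularity,
so each (orientation, angularity) class resolves to a heading pair and a
segment length: turns of roughly 20° (low), 150° (medium) and 160°
(high) with segment lengths chosen to put mean angularity near 2, 13 and
60–80 deg/px — comfortably inside the low/medium/high ranges — while the
folded orientations of both headings stay a few degrees clear of the
orientation-class boundaries. The "both" class alternates pure
horizontal and vertical segments (90° turns) and tunes angularity
through segment length alone. Segment lengths and turns are jittered
(±10%, ±3°) and rescaled so the realized length equals the target: short
contours draw targets from 48–80 px and long from 200–550 px, keeping
realized lengths strictly on the intended side of the 87.10-px split.
Under these margins the generator/classifier agreement is effectively
exact; the audit in `synth_pool()` requires ≥ 99%.

**Free random contours** (`synth_random_contour()`) draw lognormal
segment lengths and Gaussian signed turns with per-contour scales, so a
set of drawings spreads mass over all histogram bins; they feed the
regression studies, where feature variety rather than bin purity
matters.

**Rating data** follow `clip(5 + Xβ* + N(0, σ), 1, 9)` with X the
sqrt-transformed features. The default β* is sparse — vertical pixels
−0.03, long-contour pixels +0.01, highly angular pixels −0.08 per
sqrt-pixel — i.e. effects of the sign and magnitude scale reported for
traced photographs, small enough that well under 1% of ratings clip
(the realized clip fraction is reported). Replicated studies resample
only the noise over a fixed design: X is ancillary to the coefficient
estimates, so regenerating drawings each replicate would add Monte Carlo
cost without information.

**Choice sessions** partition the 480 stimuli into 120 four-image trials
per participant (each image exactly once) and pick the argmax/argmin of
cell utility + participant intercept + standard Gumbel noise — the
classic discrete-choice device. Because the participant intercept is
common to the four images in a trial it cancels from the argmax, and the
fitted participant SD on such data is near zero; the binary logistic
model is a deliberately misspecified but directionally consistent
analysis of 4AFC data. Exact-recovery tests therefore use
**bernoulli-direct** mode (`synth_choice_observations()`), which draws
outcomes straight from the logistic model so the fitted coefficients
have a well-defined truth (`observer_fixef()` projects cell utilities
onto the sum-to-zero basis).

## Interface

The package's interface is its functions plus the numbered driver
scripts under `analysis/`, which narrate the workflow end to end
(simulate ratings, fit the regression, build stimuli, simulate sessions,
fit the choice model) and write their tables under `results/`. All file
formats — the JSON drawing dialect, SVG polylines, and the feature,
rating, manifest, trial and result CSVs — have reader/writer pairs that
round-trip, so every pipeline stage can be driven from files as well as
from R objects. There is no separate shell wrapper: the drivers are the
command-line surface.

## Validation suites and problem sizes

The acceptance tests run, per suite: geometry against an independently
coded brute-force oracle on 200 random polylines (1e-9 relative);
histogram conservation on 100 random drawings (1e-6); regression
recovery on one 1182-image design with 200 noise replicates (±2 SE
coverage pooled over the 23 coefficients ≥ 93%) and 500 null replicates
(overall-F type-I rate in [0.03, 0.07] at α = 0.05); GLMM recovery at
157 participants × 240 observations over 20 replicates (median fixed
effects and participant SD within ±0.1 of truth), the zero-variance
logistic oracle at 1e-3, and per-effect LRT type-I rates over 200 null
replicates at a reduced size of 16 participants × 120 observations
(α = 0.05 rate within [0.02, 0.09]); and 20 end-to-end seeds at 157
participants in which all three main-effect LRTs must reach p < 0.001
with the simulated signs. The reduced sizes for the replicated null
studies keep each replicate's cells well populated (≥ 80 observations
per design cell) while the replicate count, not the per-replicate size,
drives the precision of the estimated error rates.

## What passing does and does not show

The synthetic generators emulate the *geometric and statistical
structure* the analyses assume: controlled feature composition, linear
rating effects on sqrt-features, logistic choice behaviour with
participant heterogeneity. They do not emulate semantic content, the
biases of human artists tracing photographs, category structure among
photographs, response times, or inattentive participants. Passing
therefore shows that the pipeline's machinery is correct and calibrated
— that it recovers truth when its assumptions hold — not that the
substantive findings would replicate in new human data. The printed
statistics of the original human studies are not reproduction targets
here: they depend on an access-restricted image set and external crowd
data.

Known limitations: angularity is a per-vertex turn measure, not
differential-geometric curvature, and is sensitive to how densely a
tracing places fiducial points; the stimulus bins assess membership
before placement, so shortened contours can drift; and the 4AFC
simulator's Gumbel choice rule is one of several defensible observer
models (its qualitative predictions, not its likelihood, are what the
pipeline tests).
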