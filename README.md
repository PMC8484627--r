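# contouraffect

Tools for studying how mid-level contour statistics of scenes relate to
human judgements of emotional valence and threat.

## The scientific problem

People judge, within a glance, whether an environment looks pleasant or
threatening. One hypothesis is that such judgements track mid-level
contour features that also cue scene layout: the *orientation*, *length*
and *angularity* (sharpness of turns) of the lines that make up a scene.
This package implements a complete analysis pipeline around that
hypothesis:

1. **Feature extraction.** A line drawing is a set of contours — open
   polylines of fiducial points on a pixel canvas. For each drawing the
   package computes three pixel-weighted 8-bin histograms:
   - *orientation*: each segment contributes its length at its
     counter-clockwise angle from horizontal (bin centers 0°, 22.5°, …,
     157.5°, circular);
   - *length*: each contour contributes its total length at log10(length)
     (bin centers 1.66 … 1698.24 px, log-spaced);
   - *angularity*: each interior vertex contributes its adjacent
     half-segments at log10(turn angle / mean adjacent segment length)
     (bin centers 1.38 … 131.83 deg/px).
   Concatenating the histograms and dropping the sparse Length-8 bin
   gives a 23-dimensional feature vector, square-root transformed to tame
   outliers.

2. **Valence regression.** Ordinary least squares of per-image mean
   valence ratings (1 = unhappy … 9 = happy) on the feature vector, with
   partial-regression (added-variable) outputs and separate fits for
   "close" (object-dominated) and "far" (scene-background) images.

3. **Stimulus construction.** Contours are classified into a
   2 (length) × 3 (angularity) × 4 (orientation) factorial of 24 bins and
   assembled into abstract 200×150-px scenes: coordinates divided by 4
   (a contour starting at pixel [400, 300] starts at [100, 75]), shifted
   or shortened to fit, and appended until each image exceeds 1000 px of
   contour; 20 images per bin, 480 in all.

4. **Choice analysis.** Four-alternative forced-choice sessions (120
   trials of 4 images; each image shown once) are expanded into binary
   observations — the chosen most-positive/safest image scores 1, the
   chosen most-negative/most-threatening 0, neutrals are excluded — and
   modelled by random-intercept logistic regression
   (logit P(positive) = Length × Angularity × Orientation factorial,
   sum-to-zero contrasts, Gaussian participant intercepts, Laplace
   approximation) with per-effect likelihood-ratio tests.

5. **Synthetic data.** Because the original photographs are
   access-restricted and the human ratings are external, a first-class
   synthetic module generates every input with known ground truth:
   bin-targeted contours (directed random walks), free random drawings,
   ratings from a known linear model, and simulated observers (utility +
   Gumbel noise, or bernoulli-direct for exact recovery tests).

## Worked example

The `analysis/` directory holds the numbered workflow. Running

```sh
Rscript analysis/01_simulate_valence_data.R
Rscript analysis/02_fit_valence_model.R
```

simulates 1182 drawings with true effects β(O5) = −0.03, β(L7) = +0.01,
β(A8) = −0.08 per sqrt-pixel and refits them:

```
Valence regression: n = 1182, R^2 = 0.0489, F(23, 1158) = 2.589, p = 6.078e-05
partial slope O5: -0.0473 (multiple-regression beta -0.0473)
partial slope L7: +0.0115 (multiple-regression beta +0.0115)
partial slope A8: -0.0364 (multiple-regression beta -0.0364)
```

The overall fit is significant with a small R² — individually weak
feature effects of the designed sign, recovered within sampling error —
and the partial-regression slopes equal the multiple-regression
coefficients (the Frisch–Waugh identity, asserted in the tests).

```sh
Rscript analysis/03_generate_stimuli.R
Rscript analysis/04_simulate_choices.R
Rscript analysis/05_fit_choice_model.R
```

builds the 480-image stimulus set, simulates 157 participants per task
with observers that prefer long, smooth, horizontal contours, and fits
the choice model:

```
== valence task ==
                        effect   chisq df        p
                        Length 3668.28  1 0.00e+00
                    Angularity 3443.96  2 0.00e+00
                   Orientation 2624.00  3 0.00e+00
             Length:Angularity   26.15  2 2.09e-06
            Length:Orientation   12.16  3 6.86e-03
        Angularity:Orientation   21.16  6 1.72e-03
 Length:Angularity:Orientation    5.61  6 4.68e-01
most positive cell:  long/low/horizontal (prop 0.96)
most negative cell: short/high/both (prop 0.14)
```

All three main effects are overwhelmingly significant with the simulated
directions (long > short, low > high angularity, horizontal > other
orientations); in the threat task the Length effect dominates
(χ²(1) = 14686.8). Per-cell choice proportions and fixed effects are
written under `results/`.

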