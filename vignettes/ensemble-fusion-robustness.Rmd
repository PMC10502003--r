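---
title: "Fusing segmentation ensembles and quantifying their robustness"
author: "ensembleseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing segmentation ensembles and quantifying their robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ensembleseg)
```

## The problem

An ensemble of J independently trained segmentation models produces J
binary masks for the same 3-D image. Averaged voxel-wise, these masks form
a probability map: the fraction of models that call each voxel foreground.
Two questions drive this package. First, how should the J candidates be
combined into a single consensus mask, and how much does the choice of
combination scheme matter? Second — often more important in a medical
setting — how effectively does combining suppress the rare *catastrophic
failure* of an individual model, such as a spurious component segmented
tens of millimetres from the organ?

All computations operate on co-registered binary masks with per-axis voxel
spacing in millimetres. Registration, resampling and intensity handling
are deliberately out of scope: geometry mismatches between masks of one
image are an error, never silently repaired.

## Evaluation metrics

Four standard metrics compare a prediction A against a reference B:

* **DSC** `= 2|A∩B| / (|A|+|B|)` — relative overlap, in [0, 1].
* **RVD** `= ||A|−|B|| / |B|` — volume agreement ignoring overlap. The
  absolute value is used so RVD can be aggregated as a loss; a signed
  variant is available (`rvd(signed = TRUE)`).
* **ASSD** — the mean, over the union of both directed multisets, of
  nearest boundary-to-boundary distances, in mm.
* **MSSD** — the maximum of those distances: the Hausdorff distance
  between the two boundaries. This is the metric most sensitive to
  spurious components, which dominate its value however small they are.

Boundaries are foreground voxels with at least one background 6-neighbour,
the grid border counting as background. Distances come from an exact
anisotropic Euclidean distance transform (separable lower-envelope
algorithm, implemented in C++), so a voxel spacing of (1, 1, 5) mm yields
genuinely 5× larger axial steps; the test suite checks agreement with an
all-pairs brute force to 1e-9 mm.

Degenerate masks take documented finite values instead of crashing: both
masks empty is perfect agreement (DSC 1, RVD 0, distances 0); exactly one
empty mask yields DSC 0, RVD 1 (empty prediction) or undefined (empty
reference), and surface distances capped at the grid's physical diagonal.
The `surface_defined` flag records every fallback. The cap keeps
catastrophic empty predictions *rankable* — they must land beyond any
outlier boundary, not vanish as `NaN`.

## Fusion schemes

* **Averaging + threshold** (`average_probability()`, `threshold_mask()`):
  the consensus is `mean_j S_j >= p_thr`, with ties at exactly `p_thr`
  counting as foreground (a fixed convention; the alternative is equally
  defensible but must be chosen once). The default `p_thr = 0.35` is the
  threshold that maximises ensemble Dice on average across organs in the
  source domain; `sweep_threshold()` recomputes the whole curve for any
  study.
* **Majority vote** (`majority_vote()`): strictly more than half of the
  votes; an even-J tie is background. For odd J this is provably identical
  to averaging thresholded at `0.5 + eps` for any `eps` in `(0, 1/(2J)]`,
  which the tests verify exhaustively over all single-voxel vote patterns
  for J = 3 and 5.
* **STAPLE** (`staple()`): a binary EM model in which rater j has latent
  sensitivity `p_j` and specificity `q_j` and raters are conditionally
  independent given the latent truth. The E-step computes per-voxel
  posterior weights `W_i`; the M-step re-estimates `(p_j, q_j)`.
  Numerical choices: all likelihood products in log space; parameters
  clamped to `[1e-7, 1 − 1e-7]`; scalar foreground prior defaulting to the
  mean foreground fraction of the inputs (a spatially varying prior is a
  known extension, not implemented); `init_p = init_q = 0.9`;
  convergence when the change of `sum(W)` per voxel drops below
  `tol = 1e-6`, capped at 100 iterations. The observed-data log-likelihood
  is recorded per iteration and asserted non-decreasing (the EM guarantee)
  in every test run. Binarisation of `W` at 0.5 by default; for a sharply
  converged fit any threshold well inside (0, 1) gives nearly the same
  mask.
* **Regression combiner** (`fit_regression_combiner()`): per model m, an
  ordinary least-squares fit of its ground-truth Dice on its J−1 pairwise
  Dices across training images; at prediction time the candidate with the
  highest predicted score wins, ties resolving to the lowest model index.
  The fit requires `n_train >= J` and a full-rank design (identical
  candidates across all training images are rejected with the model
  named); an optional ridge penalty (default 0) is available for
  near-collinear ensembles.

## Robustness analytics

Outliers are defined per organ and metric on the pooled (image × model)
single-model distribution: DSC below its 5% quantile, RVD/ASSD/MSSD above
their 95% quantiles (`percentile` configurable; `pooling = "per_model"`
switches to per-model boundaries, since pooling across models is itself a
modelling choice). Quantiles interpolate linearly between order statistics
(type 7), and an observation is an outlier only *strictly* beyond the
cutoff, so an all-equal sample has none. Fused masks are always flagged
against the single-model boundaries, never their own distribution.

A *high-risk image* is one where at least one single model produced any
outlier metric; the *rescue rate* is the fraction of high-risk images on
which the fused mask is outlier-free, reported per metric. An empty
high-risk set yields an explicit null result rather than 0 or 1.

Ensemble gain is computed on losses (Dice loss `1 − DSC`, RVD, ASSD,
MSSD): `g = L_ens − L_ref` per image, with the reference either the mean
or the worst single model; negative gains are improvements. The trend of
gain against single-model loss is fitted with the **York**
errors-in-both-variables estimator: minimise
`sum_i W_i(b) (y_i − a − b x_i)^2`, `W_i(b) = 1/(sy_i² + b² sx_i²)`,
iterating the slope from the OLS start until `|Δb| < 1e-10` (cap 200
iterations), with parameter standard deviations from the standard
adjusted-point variance expressions. With `sx = 0` and constant `sy` the
estimator reduces exactly to OLS; the tests also compare it against a
brute-force grid minimisation and check that `slope ± 2 sd` covers a known
true slope in at least 90 of 100 simulations. In `gain_fits()` the
per-image coordinate uncertainties are the standard errors of the model
losses within that image's ensemble.

`subsample_ensembles()` draws, for each requested size, `n_rep` uniform
subsets of the models without replacement (distinct subsets whenever
enough exist), fuses each by averaging + threshold and summarises the
metrics over repeats; everything is reproducible from one seed.

## The synthetic study generator

The generator emulates the statistical structure the analytics assume,
not anatomy:

* **Phantoms**: ellipsoids (analytic; default semi-axes 14 × 11 × 9
  voxels on a 64³ grid at 1 mm³) or thresholded smoothed-noise blobs for
  organic outlines. Per-image variation scales the semi-axes by ±20% and
  shifts the centre by up to 3 voxels, creating genuinely easier and
  harder images — which is what lets per-image difficulty cluster, as it
  does in real data.
* **Model outputs**: an affine jitter of the truth (rotation ≤ 5° and
  scaling ≤ 5% per axis — ranges with a direct counterpart in the training
  augmentation of the source domain — plus translation ≤ 2 voxels; a
  translation range quoted for 192-voxel crops must shrink with the grid
  and organ radius, and ±2 voxels reproduces mid-band single-model
  accuracy at 64³), followed by 0–2 dilate and 0–2 erode passes that each
  flip a random 20–60% of the boundary layer with a random (6- or
  26-neighbourhood) structuring element. A *full* morphological layer on a
  ~10-voxel-radius phantom would change the volume by tens of percent —
  gross failure, not boundary noise — hence the partial flips.
* **Catastrophic failures**, independently per (image, model):
  with `p_spurious = 0.05` a disconnected ellipsoidal component of 64–512
  voxels is injected at least 20 mm from the truth (placement that cannot
  satisfy the distance constraint is an error naming it); with
  `p_dropout = 0.02` a connected chunk of 20–50% of the organ around a
  random boundary seed is deleted. Which failures fired is recorded on
  each mask, and the per-image count of spurious-failure models is
  checked against the implied binomial law.
* **iid raters** (`simulate_rater()`): each true-foreground voxel kept
  with probability `sensitivity`, each background voxel flipped on with
  probability `1 − specificity` — exactly STAPLE's generative model, used
  for the parameter-recovery tests (J = 8 raters at 0.90/0.95 on a 48³
  phantom are recovered within ±0.02).

Seeds are hierarchical: every mask is a pure function of
`(master seed, image index, model index)` and can be regenerated in
isolation.

**What passing tests do and do not show.** The generator's failures are
independent across models, spatially random, and sit on geometrically
simple organs. Real ensemble members are trained on largely the same data,
so their errors correlate; real organs have thin structures and ambiguous
boundaries. Consequently the synthetic studies validate the *machinery*
(metrics, fusion, outlier logic, estimators) and reproduce the *direction*
of the domain's findings — ensembles raise mean accuracy a little and cut
worst-case surface distances a lot, gains grow with per-image difficulty,
benefits saturate near 8–10 models — but none of the magnitudes transfer,
and independence makes ensembling look somewhat stronger here than
correlated real-world ensembles can be.

Two desk-scale artifacts deserve explicit mention. With quantile-defined
outliers, about 5% of the pooled observations are flagged per metric by
construction, and with cross-model independence those flags scatter over
many images: the default study's high-risk fraction (reported by
`scripts/acceptance.R`) is therefore far larger than the ~10–15% one would
see with strongly image-correlated failures. And at 64³ the ensemble's
probability ramp spans a sizeable fraction of the organ radius, so the
mean-DSC-versus-threshold curve is markedly steeper over `p_thr` in
[0.25, 0.5] than the near-flat plateau seen for large organs on 192³
grids; the optimum's *location* (mid-range, around 0.45 here) is
reproduced, its *flatness* is not. Both are properties of scale and of the
independence assumption, not of the implementation.

## Problem sizes

The default study is 40 images × 16 models on a 64³ grid — large enough
for stable quantile boundaries (640 pooled observations) and Spearman
trends at n = 40, small enough that a full simulate–fuse–evaluate cycle
takes well under a minute. The acceptance checks replicate it over ten
master seeds; STAPLE recovery uses 48³, the surface-distance oracle runs
on ≤ 16³ grids where the all-pairs brute force is exact and fast. 192³
grids are supported throughout, only slower.

## Known limitations

* Single-label (binary) masks only; no multi-organ STAPLE.
* No learned combiner beyond the pairwise-Dice regression; no trained
  auxiliary network.
* The STAPLE prior is a spatial scalar; no Markov or atlas prior.
* Outlier boundaries assume enough observations per organ for a stable
  5%/95% quantile; with fewer than ~20 observations the strict-inequality
  rule flags little.
* Kruskal–Wallis comparisons between schemes are delegated to
  `stats::kruskal.test` by the user; the package reports the per-scheme
  summaries (`compare_methods()`) they would operate on.
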