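---
title: "Topographic analysis of forest–savanna mosaics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic analysis of forest–savanna mosaics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaictopo)
```

## The question and the analysis design

Forest (closed tree cover) and savanna (open tree cover) can coexist as
alternative stable vegetation states. Within a single ~10 km landscape,
climate is effectively constant, so any systematic spatial sorting of
the two covers must be driven by finer-scale structure — and topography
is the leading candidate: valleys can act as fire refugia or waterlogged
exclusion zones, crests dry out, slopes channel fire and water.
`mosaictopo` frames that as a prediction problem: *how accurately can a
pixel's cover state be predicted from local terrain alone, and through
which terrain features, with what sign?*

The chain is: derive six topographic predictors from elevation; binarize
percent tree cover and tile the region into landscapes; class each tile
by composition; fit a *regional* classifier pooled across all mosaic
landscapes and a *local* classifier per landscape; and summarise each
fitted model by held-out accuracy, impurity feature importance, and the
direction/monotonicity of its Accumulated Local Effects (ALE) curves.
Every stage is seeded, and per-tile substreams are derived
deterministically from one master seed, so a whole run is reproducible
from its configuration (the pipeline manifest records content hashes of
every output to make this checkable).

## Terrain features

The six predictors are the topographic position index at three
neighbourhood radii, slope, and the two aspect components.

**TPI.** `TPI_r(p) = elev(p) − mean(elev over a square window of side
2·round(r / cell) + 1 centred on p)`, centre included, edges mirrored
(with edge repetition), nodata excluded from the mean. The window is
square — a box filter — rather than a disc: the scale interpretation is
unchanged and the operator is exactly a uniform filter, computed here in
O(N) with a summed-area table (the suite checks it against a literal
per-pixel loop to 1e-9). Positive TPI marks crests, negative marks
depressions; the three radii (50 m, 500 m, 5000 m at 30 m cells)
separate micro-relief from hillslope and massif scale.

**Slope and aspect.** Horn's 3×3 finite-difference stencil gives the
gradient; `slope = atan(|∇z|)` in degrees. Aspect is the compass
direction of the downhill vector, returned as `aspect_sin` (eastness)
and `aspect_cos` (northness) so the circular quantity enters models
continuously. Flat cells get the sentinel `(0, 0)` rather than nodata so
no pixel loses its feature vector; border cells use clamped (replicated)
edges. These conventions — window shape, centre inclusion, edge
policies, the flat-cell sentinel — are deliberate, documented choices;
each is pinned by an oracle test rather than inherited silently from a
library.

**Roughness** of a landscape is the population standard deviation of its
valid elevations — the single number used to relate model skill to
relief.

## Landscapes

Percent cover is binarized at a threshold: the package default is 65,
the value appropriate to continental tree-cover products where the
bimodal distribution of cover has its inter-mode minimum near 65%;
`find_bimodal_threshold()` can instead locate that minimum per dataset
(kernel density with Silverman bandwidth; two modes are required, and a
candidate pair whose trough is shallower than 90% of the lower peak is
rejected as a unimodal ripple). A pixel is closed when cover is
*strictly above* the threshold — the boundary convention is tested
explicitly. Tiles are square, non-overlapping, with trailing partial
tiles dropped (a partial tile would have biased composition fractions).
A tile is *excluded* below 75% valid pixels; otherwise *mosaic* when the
closed fraction over valid pixels is within [0.05, 0.95] (inclusive at
both ends), else homogeneous. Cover fractions are computed over valid
pixels, validity over all pixels: exclusion and composition are
independent questions.

## Sampling and models

The regional sample takes 5 open + 5 closed pixels per mosaic landscape,
uniformly without replacement — stratification that makes the model
learn *within-landscape configuration* rather than among-landscape
composition (which climate, not topography, governs). A tile that cannot
supply a full quota contributes equal, reduced numbers of both classes;
shortfalls are recorded. Local models draw 5000 pixels per tile, evenly
split; when the minority class is smaller, both classes shrink to it,
and below 50 per class the tile is skipped with a logged reason. All
sets are split 80/20, stratified by label — local models reuse the same
split discipline as the regional one.

The classifier is a probability random forest with exactly three pinned
hyperparameters — 100 trees, minimum 10 samples per leaf, maximum depth
10 — run single-threaded with a fixed seed so fits are bit-reproducible.
The ensemble engine is `ranger`; the package owns the contract around it
(feature order, class order, the soft-vote probability used downstream,
normalized impurity importances with a lexicographic tie-break for the
top feature) and the remaining engine defaults are recorded on the
fitted object. A balanced two-class problem makes 0.5 the chance-level
accuracy against which everything is read.

## Accumulated Local Effects

ALE is implemented from its definition rather than delegated, because
the downstream statistic operates on the raw curve. The feature is cut
at empirical quantiles into 20 bins (duplicate edges from heavily tied
features are merged, weights pooled); the local effect of a bin is the
mean prediction difference when the feature is moved from the bin's
lower to upper edge with all other features held at observed values;
effects are accumulated and centred by the bin-count-weighted mean.
Quantile bins keep every bin populated under skewed features; the
centring makes curves comparable across models. A constant feature
yields a flagged zero curve instead of an error, so degenerate tiles
(e.g. flat terrain) stay in the books.

The *effect direction* is the Spearman correlation of bin centres with
ALE values: sign = direction of the effect on closed-cover probability,
magnitude = monotonicity. It is computed unweighted, one point per bin —
a correlation of the plot, not of the data. The companion
`abs_effect_direction()` correlates `|centre|` with the curve, catching
symmetric V-shaped responses (cover favoured at both extremes of a
feature) that the signed statistic averages to zero. The suite checks
the implementation against a literal double-loop oracle to 1e-12 and
against closed-form linear and additive models.

## Synthetic ground truth

The generator exists so that every downstream claim can be tested
against a known answer.

**Terrain** is spectral synthesis: white noise filtered in the Fourier
domain to a power-law spectrum `P(k) ∝ k^−β`, rescaled to an exact
target standard deviation (the `amplitude`). β ≈ 2.5 resembles natural
topography; larger is smoother. Periodic boundary artefacts are accepted
since every analysis is local. Defaults (30 m cells, 15 m amplitude)
match the resolution of global elevation products and a moderate-relief
mosaic region.

**Vegetation** follows a logistic model on standardized features:
`eta = intercept + Σ coef·z(feature) + ε`, with the closed-cover
propensity `plogis(eta)`. Standardizing features inside the generator
makes coefficients comparable across features, so "which feature
dominates" is well-defined ground truth. The noise field ε (given sd,
optional spatial correlation via box smoothing) is the *only* stochastic
component of the labels: a pixel is closed exactly where `eta > 0`
(exact ties — possible only in the fully degenerate zero-logit case —
fall to a fair coin). This makes `noise_sd` a clean dial on the
achievable classification accuracy: at `noise_sd = 0` cover is fully
determined by topography and a good pipeline should approach perfect
recovery; drawing labels as independent Bernoulli trials instead would
impose an irreducible accuracy ceiling (≈ 0.89 at coefficient 5) that no
model could pass, muddling parameter-recovery tests. Percent cover is
then drawn per label from a two-mode normal (defaults 20% and 90%,
sd 8) and clipped to [0, 100], reproducing the bimodal distribution that
motivates thresholding; the label/percent pair stays consistent
(midpoint thresholding recovers ≥ 99% of labels when the modes are more
than four standard deviations apart).

**Feedback-only cover** is the null: a smoothed noise field thresholded
at the empirical quantile of the target closed fraction, giving patchy
cover statistically independent of any elevation field — what a mosaic
maintained purely by internal feedbacks (fire spread, vegetation memory)
would look like.

What the generator does *not* emulate: drainage networks and hydrologic
organisation, fire spread dynamics, anthropogenic fragmentation, and the
heavy-tailed relief of real continental terrain. Passing tests therefore
demonstrate that the pipeline recovers planted topographic signal and
reports chance under independence — not that real landscapes behave like
the generator.

## Calibration, problem sizes and a caveat on spatial leakage

The test suite validates the chain at deliberate desk scales: oracle
grids up to 50×50; parameter recovery on twenty 64×64-pixel landscapes
(a single driver, coefficient −5 on TPI_500m, zero noise → mean local
accuracy ≥ 0.95, the driver top-ranked with direction ≤ −0.9 in at least
18 of 20 tiles, sign-flip symmetric); a null calibration averaging ≥ 20
seeded replicates of 2000-pixel balanced samples with permuted labels
(mean held-out accuracy 0.5 ± 0.02); and a byte-identical rerun of the
full pipeline on a six-landscape demo under one master seed.

One empirical subtlety deserves record. With *spatially patchy* cover
that is independent of topography **by construction**, local models on
rough terrain still score ≈ 0.55–0.6, not 0.5: smooth features (TPI at
large radii) are effectively coordinates, and when training and test
pixels interleave within one tile the forest memorises the realised
patch layout through them. That is spatial leakage, a real property of
interleaved within-landscape validation — worth remembering when
reading local accuracies near chance on real data. The package's null
checks therefore either remove the information channel (flat terrain,
where all features are constant) or sever the association row-wise
(label permutation); both calibrate to 0.5 exactly as expected.

## Known limitations

- No geodesy: grids live in a projected local frame with constant
  metres/pixel; the ~0.1° landscape is a configurable pixel tile
  (default 333 at 30 m). Reprojection and geographic rendering are out
  of scope.
- On-disk formats are plain-text grids (ESRI ASCII, headered CSV);
  masks are abstract validity rasters, not land-cover class semantics.
- The composition subsets ("mostly open / balanced / mostly closed")
  default to thirds of the closed fraction — a configurable convention,
  not an estimated boundary.
- Local models use a random stratified 80/20 split; spatially blocked
  validation (which would suppress the leakage discussed above) is
  deliberately not implemented, to keep the local protocol identical to
  the regional one.
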