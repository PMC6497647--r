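---
title: "Informational network neural scores: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informational network neural scores: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infonetscore)
```

# The problem

A learner who has acquired a concept — say, how mechanical structures carry
load — categorizes the world along dimensions a novice cannot see. If that
category structure is represented anywhere in the learner's brain, the
item-by-item geometry of their activity patterns should reflect it, and a
scalar summary of that geometry becomes a *neural score* of concept
knowledge, complementary to a written test. This package implements such a
score and two standard comparators, end to end, with a synthetic cohort
generator that plants the relevant structure so every stage can be verified.

Throughout, the stimulus world is 24 items in 3 mechanical categories
(cantilevers, trusses, vertical loads), 8 items each, with a second,
*visual* similarity dimension deliberately crossing the categories.

# Data model

The atomic input is an `item_beta_maps` object: one GLM coefficient per item
per in-mask voxel for one subject and run, plus the residual variance,
residual degrees of freedom and the unscaled coefficient covariance
`(X'X)^-1` of the fit. These three extras matter: contrast z-maps must be
built on the *residual* (temporal) noise of the GLM, not on the spread of
the item betas — the item-level pattern structure is signal, and using
item spread as error would leak pattern amplitude into the univariate
statistic (see "Why the dissociation works" below).

Pairwise pattern dissimilarity is the correlation distance
`d = 1 - Pearson r`, stored condensed (row-major upper triangle, 276 values
for 24 items); the ordering is shared by every consumer, including
`stats::dist`, preventing silent pair misalignment. Pearson (not rank)
correlation matches the convention of the volumetric searchlight toolchains
this pipeline mirrors; it is configurable at the few places a different
distance could enter.

# The three scores

## Univariate

The images-greater-than-baseline contrast is averaged over item regressors,
converted per voxel to t and then to z by probability matching through the
t distribution at the fit's dof (at the simulated dof of ~270 this differs
from "treat t as z" only in the far tail, but it is the principled choice
and costs nothing). The "robust range" is interpreted as the top 2% of
voxels by *positive* z — the prose rule of the protocol this package
follows — implemented as `z >= k-th largest positive z` with
`k = ceiling(f * n_positive)` and ties included. The score is the mean z
over that mask.

## Searchlight RSA

Searchlights are spheres in voxel-index space. The nominal "radius = 100
voxels" of the source description is read as a ~100-voxel sphere *volume*:
a radius of 3 voxels gives 123-voxel interior spheres, and the radius is a
config knob. (Read literally, a 100-voxel radius would cover any brain.)
Each searchlight DM is compared with the 24-dimensional expert model by
Spearman correlation (average ranks on ties); Fisher z values at or above 2
are averaged. A Spearman z of 2 corresponds to rho ≈ 0.964, so on noisy
data most subjects have no surviving location; they are flagged `dropped`,
exactly mirroring the source protocol, which dropped two participants this
way. A perfect rho = 1 would give infinite z; it is capped at
`atanh(1 - 1e-16)` ≈ 18.71 and flagged rather than dropped, so a degenerate
perfect-match subject still yields a finite record.

## Informational network

The pipeline: robust-range mask → searchlight DMs at surviving centers →
average-linkage clustering of the condensed DMs (distance = 1 − correlation
between DM vectors) → multiscale bootstrap → AU-reliable networks → per
network, average DM → classical 2-D MDS → radial SVM on the 3 category
labels → score = best network's accuracy.

The multiscale bootstrap resamples the *coordinates* of the condensed DM
(the feature axis), mirroring the cited clustering tool's resampling of
rows while clustering columns; the observation axis (searchlights) is what
is being clustered, so resampling it would change the objects themselves.
For scales r in {0.5, …, 1.4}, `ceiling(r * p)` coordinates are drawn with
replacement, the tree is rebuilt, and each reference node's member set is
checked for exact recovery. The per-node recovery curve BP_r is fit by
least squares as `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` over scales
with 0 < BP_r < 1, and `au = 1 - pnorm(v - c)`. Degenerate curves (never or
always recovered) are assigned au = 0 or 1 and flagged rather than fitted.

Two structural decisions deserve notice:

* **The root is never a candidate network.** Every replicate tree trivially
  contains the all-observations set, so the root's support is always 1 and
  carries no information; admitting it would collapse every subject to a
  single network. The root is returned only as an explicit fallback (with a
  warning and a `fallback` flag) when no node reaches the AU threshold, so
  a score is always produced. This matches the reference implementation of
  the clustering method, whose cluster-picking routine also skips the top
  edge.
* **AU versus BP.** AU deliberately corrects the size-dependent bias of the
  ordinary bootstrap proportion; the two measures therefore do *not* agree
  in rank order across arbitrary nodes (we verified the same disagreement
  in the reference implementation). What does hold, and what the tests
  assert, is that BP falls monotonically as planted structure gets noisier
  and that both measures rank genuinely planted nodes above noise nodes.

MDS is classical (Torgerson) by default: deterministic, exact for
Euclidean-realizable DMs, and adequate as the noise-reduction step it is
meant to be; a stress-minimizing nonmetric variant (initialized from the
classical solution, fixed iteration cap) is available. Eigenvalues below
`1e-8` of the leading one are treated as nonpositive and their coordinates
zero-padded with a warning, so degenerate DMs embed reproducibly.

The SVM is a radial-kernel soft-margin machine (one-vs-one voting, cost 1,
kernel width `gamma = 1/n_features = 0.5` in 2-D — the defaults of the
standard implementation, fixed so the score stays a fixed statistic). The
solver is a deterministic SMO implementation: fixed sweep order,
second index by maximal `|E_i − E_j|`, ties to the lowest index. On the
24-point problems this package faces it agrees with libsvm's predictions
(validated during development on hundreds of random 3-class problems).
Accuracy is resubstitution over all 24 items by default — the wording
"predicted category labels for each item in a given DM" describes
prediction on the very items the machine saw, and resubstitution keeps the
score a property of the network's geometry rather than of a resampling
scheme; leave-one-out is available as `eval_mode = "loo"`. Ties on the
maximal accuracy break toward the larger network, then the lower merge
height, making the argmax deterministic.

# The synthetic world

`generate_cohort()` plants, per subject and run:

* **Task blobs** (default 2, radius 3): every item adds `a_task = 3` beta
  units — task engagement without item information.
* **Informational blobs** (default 2, radius 3): item patterns
  `w_cat * e * mu[cat(i)] + w_vis * nu[vis(i)]`, where the `mu` are 3 fixed
  orthogonal category prototypes, the `nu` are visual-cluster prototypes
  orthogonal to the `mu`, and `e` in [0, 1] is the subject's latent
  expertise. These voxels also receive `a_task`, which is what lets the
  univariate robust-range mask find them.
* **Noise**: i.i.d. `N(0, 1)` per item-voxel, plus simulated GLM
  residual-variance estimates (`sigma^2 * chi2_270 / 270` per voxel), so
  contrast z-maps behave like real first-level output.

Amplitudes are free parameters of the stated world (no effect size is
published for the neural signal); `a_task = 3, w_cat = 1.2, w_vis = 0.8,
noise_sd = 1` were chosen once as a moderate-SNR regime in which the
planted geometry is recoverable but far from noise-free — searchlight DM
entries at full expertise differ by ~0.1–0.3 between within- and
between-category pairs against a sampling noise of ~0.13.

Two subtleties make the world honest:

* **Prototype centering.** Each prototype set is centered across its
  (item-count-weighted) classes, so the item-*mean* pattern is exactly zero
  at every voxel. Without this, the category patterns would shift the
  images-greater-than-baseline contrast and expertise would leak into the
  univariate score, destroying the planted dissociation for a reason that
  has nothing to do with the scores themselves.
* **Balanced visual clusters.** In the default 24-item design the 8 visual
  clusters each hold 2 items of one category and 1 of another, arranged so
  same-cluster pairs split 8 within- / 16 between-category — essentially
  the marginal 84:192 ratio. Visual similarity then links every item to an
  item of a different category (as the stimulus design intends) while
  leaving the expected within-minus-between category distance at zero when
  `e = 0`. A naive striping of clusters across categories would make
  between-category pairs systematically more similar and bias the gap.

Behavior is linear in expertise with accuracy noise of 0.05: FBD accuracy
`0.45 + 0.40 e` (novice ≈ 0.54, expert ≈ 0.75 at the group means of a
thresholded-at-0.5 world, echoing the published run-1 scale), SCI
`0.10 + 0.55 e`, FCI `0.25 + 0.60 e`, each inventory missing with
probability 1/3 (the published cohort lost about a third of each).

What the generator does **not** emulate: temporal autocorrelation and
prewhitening (the pipeline consumes betas; residual structure never
enters), scanner drift, motion, anatomical variability, surface topology
(localization stays on the shared volumetric grid), and any nonlinearity
between expertise and behavior. A green end-to-end test therefore
establishes that the *pipeline* recovers planted structure at realistic
SNR — not that real cortex encodes mechanical categories this way.

# Validation layer

Group comparisons use Welch's t (the published fractional dofs indicate
unequal-variance tests); the degenerate both-groups-constant case returns
t = 0 by convention. Score-to-knowledge models are linear mixed models,
`accuracy ~ score + (1 | subject) + (1 | test_type)`, REML for reporting
and ML inside likelihood-ratio comparisons (the standard resolution of a
detail the source leaves open). The standardized slope is
`beta * sd(score) / sd(accuracy)`; p-values use the normal approximation of
the Wald statistic and are flagged approximate for n ≤ 30. Missing
inventory rows are simply absent — the random intercepts absorb attrition;
nothing is imputed.

# Numerical and degenerate-input policy

* Correlation distances are clamped to [0, 2] against rounding; zero-
  variance item patterns raise an error naming the item (whole-brain call
  sites drop the offending searchlight and log the count instead).
* Contrast z values are clamped at the `qnorm(1e-300)` horizon; zero
  residual variance with nonzero contrast warns and clamps.
* Bootstrap member-set recovery uses exact integer-weight fingerprints
  (sums below 2^53), bit-reproducible under a seed and collision-safe to
  ~2^-40 per tree.
* All randomness flows through explicit seeds; helpers save and restore
  the caller's RNG state.

# Known limitations

* AU p-values use the first-order multiscale fit only (no higher-order
  corrections, no multiplicity adjustment across nodes) — consistent with
  the method's common usage.
* The searchlight is volumetric and isotropic; surface-based searchlights
  and anisotropic voxels are out of scope.
* `fit_score_model` treats the 3-level test-type factor as a random
  intercept, as the source did; with 3 levels the variance component is
  weakly identified and singular fits are tolerated silently.
* The alternative score variants of the source's supplement (e.g. RSA with
  a clustering step) are not shipped; the configuration surface leaves room
  for them.
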