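---
title: "Simulating motor-network connectivity and the ensemble diagnosis pipeline"
author: "adhdconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating motor-network connectivity and the ensemble diagnosis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhdconn)
```

## Scope and intent

`adhdconn` rebuilds an ensemble pipeline for automated ADHD diagnosis from
resting-state fMRI in a form where every stage is exercised by tests. The
consortium data that motivated the pipeline cannot be redistributed, so the
package's first-class citizen is a synthetic cohort generator whose defaults
encode the statistical conditions the analysis assumes: the empirical
group-mean inter-parcel correlations of a five-region primary-motor (M1)
parcellation, site-imbalanced subtype prevalence, site-dependent IQ
missingness, low-frequency BOLD-like signals with polynomial drift, and a
small set of peripheral high-variance "motion" voxels. Everything
downstream — temporal preprocessing, connectivity and CUR feature
extraction, the classifiers, the vote, the hierarchical score, the
association models — operates on those synthetic cohorts exactly as it
would on real NIfTI inputs.

## The generator model

### Parcel signals

For a subject with diagnosis $g$, the five latent parcel signals are drawn
as $T$ independent samples of a multivariate normal with unit variances and
correlation matrix $R_i$, where

$$ z_i = \mathrm{atanh}(R_g) + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \sigma_z^2) \text{ elementwise}, \qquad
   R_i = \tanh(z_i), $$

and $R_g$ is the group target: the empirically observed mean correlation
matrix for TD, combined, and inattentive groups
(`m1_correlation_targets()`), with the rare hyperactive/impulsive subtype
(about 1% of the reference sample, for which no group row was published)
defaulting to the overall-sample matrix. The Fisher-z jitter SD
$\sigma_z = 0.2$ (`corr_sd`) matches the observed between-subject SDs of
roughly 0.15–0.21. When jitter pushes $R_i$ outside the positive
semi-definite cone it is projected to the nearest correlation matrix
(`Matrix::nearPD`); this is logged, never an error.

Every voxel of parcel $p$ shares that parcel's latent signal plus white
noise of SD `voxel_noise_sd = 0.2`. The targets are imposed on the latent
(pre-noise) signals: with the default eight-voxel parcels the noise on a
parcel mean has SD $0.2/\sqrt{8} \approx 0.07$, attenuating correlations by
under 1%, which keeps recovery of the targets well-defined. Two small,
known biases remain in the *sample group means*: the concavity of
$\tanh$ under z-jitter (about $-0.014$ at $r = 0.45$, proportionally
smaller near zero), and finite-$T$ correlation bias (about
$-r(1-r^2)/2T$). Both are far inside the $\pm 0.03$ Monte-Carlo band used
by the recovery checks at $n = 500$, $T = 150$.

### Drift, noise, sites, motion

Each masked voxel receives a random linear and quadratic drift
($a \sim N(0, 1)$, $b \sim N(0, 0.5)$ in signal-SD units over the scan) —
removed exactly by the order-2 polynomial detrend — and non-parcel voxels
carry independent unit-SD background noise. Site enters twice, both
configurable and small by default: an additive IQ offset per site
($N(0, 2)$ IQ points) and a multiplicative scan-noise factor
($e^{N(0, 0.05)}$).

Motion is modelled as planted voxels, not realistic head kinematics:
`n_motion_voxels` (default 10) voxels drawn from the periphery/CSF
compartments gain a shared scaled-t (df = 3, heavy-tailed) time course,
scaled so their variance is `variance_multiplier` (default 8) times
baseline. When `shared_direction` is set the loading signs come from one
cohort-level pattern fixed in the template, emulating a common population
direction of head motion. ADHD subjects' motion variance is further scaled
by `adhd_factor` (default 2): children with ADHD move more in the scanner,
and without a diagnosis-linked motion signal the CUR features could not
carry diagnostic information, contrary to what the reference analysis
observed. Alongside the voxels, each scan emits 36 AR(1) motion nuisance
parameters.

### Phenotypes

Counts per site-by-subtype cell are exact by construction. The default
design has one balanced site, one ADHD-heavy site, and one controls-only
site, echoing the consortium's imbalance. Latent composite IQ is
$N(110, 15)$ for TD and $N(100, 15)$ for ADHD (the sample showed ADHD
roughly two-thirds of a population SD lower); four instruments (verbal,
performance, two full-scale variants) scatter around it with SD 5 and each
goes missing independently at its site's rate (defaults 0.05 / 0.15 /
0.30). Gender skews male more strongly in ADHD (0.75 vs 0.55), handedness
is 90% right, age is truncated normal (mean 12, SD 3, range 7–20).

### What the generator does not emulate

No hemodynamic response or autocorrelated BOLD spectrum (signals are white
within the band), no spatial autocorrelation or smoothing, no realistic
scanner physics, registration error, or multi-site acquisition differences
beyond the two scalar site effects. Passing tests therefore demonstrate
that the *pipeline machinery* is correct and that effects of the planted
magnitudes are recoverable — not that the pipeline would achieve any
particular accuracy on real scans.

## Preprocessing

Three linear operations on the time-by-voxel matrix, applied in the fixed
order detrend → band-pass → nuisance regression:

* `detrend_poly` — least-squares residual on $\{1, t, \dots, t^{order}\}$,
  default order 2.
* `bandpass_filter` — an ideal discrete-Fourier mask over
  $f_{lo} \le |f| \le f_{hi}$, defaults 0.01–0.1 Hz (the conventional
  resting-state band; the original processing scripts name no cutoffs). An
  ideal mask was chosen over an IIR filter because it is exact and
  closed-form testable on integer-period sinusoids.
* `nuisance_regress` — projection on an intercept plus confounds (motion
  parameters and the CSF grand mean); rank-deficient confound sets drop
  dependent columns with a warning rather than failing.

## Features

`parcel_connectivity` returns the 10 pairwise Pearson correlations of the
parcel-mean time courses in the fixed canonical order (VL, DM, PL, AL, DL
parcels; VL_DM … AL_DL pairs), making outputs comparable across every
module. Correlations, not Fisher-z values, are the features, matching the
reference analysis.

CUR column selection is deterministic: leverage scores from the top
`rank_k` right singular vectors of the centered matrix, top-`c` columns,
ties broken by lower voxel index. The reference method names CUR but
describes a deterministic choice of the most variable time courses, so
randomized leverage sampling is deliberately not implemented. `rank_k`
defaults to `c` (20), making the total score mass equal the selection
size. The covariance feature vector is the row-major upper triangle
*including the diagonal* of the selected voxels' covariance matrix:
$c(c+1)/2 = 210$ values at $c = 20$. The count 210 is only consistent with
retaining the diagonal (C(20,2) = 190 without it), and the diagonal
carries the selected voxels' variances — the most motion-sensitive
quantity — so it is kept. The 210-vectors are stacked across subjects and
reduced to 10 principal components with a training-split-only PCA
(`pca_reduce`, column-centered SVD, deterministic sign: largest-magnitude
loading positive), then projected onto held-out subjects; the seed
connectivity vectors (all pairwise correlations of, by default, 264
seed-sphere mean courses, radius 1 voxel in synthetic space — about 5 mm
in real data) are reduced the same way. The number of components retained
from the seed matrix is not documented in the reference; 10 is used for
both reductions and is configurable (`k_pca`).

`peripheral_fraction` — the share of selected voxels in the periphery/CSF
compartments — is the package's motion diagnostic: planted-motion cohorts
score strictly higher than motion-free cohorts.

## Classifiers, ensemble, score

The random-forest model uses the 10 parcel correlations plus age, gender,
site, handedness, and composite IQ (the median of available IQ measures,
computed before imputation; remaining missing covariates are filled by
median/mode with mode ties broken by the lexicographically smallest level,
a determinism rule the reference leaves unspecified).

The two-stage boosted model fits TD-vs-ADHD on all training subjects, then
a subtype model on the *true* ADHD training subjects — "those classified
as ADHD" in the reference describes prediction time, and training stage 2
on predicted labels would leak stage-1 errors into stage-2 targets. At
prediction, stage 1 gates: a stage-1 TD call is final. Boosting and forest
hyperparameters were not recorded in the reference; conventional defaults
(500 trees; 150 rounds, depth 3, learning rate 0.1) are exposed in the
configs and every fit is seeded.

`majority_vote` takes the plurality label per subject; *any* tie among the
top counts — two-way or four-way — goes to the designated tie-breaker
model (the CUR model by default, which had the best internal accuracy in
the reference). No class reweighting is applied by default: the reference
sample's TD majority pushed its models toward TD, and reproducing that
behaviour is intentional.

Scoring: 1 point for an exact match, 0.5 for true-ADHD/predicted-ADHD with
the wrong subtype, 0 otherwise — including a TD subject predicted as any
ADHD subtype, the only reading consistent with the stated rule. Binary
metrics collapse subtypes; conditional subtype accuracy is computed only
over ADHD subjects whose ADHD status was correctly detected, and
undefined denominators yield `NA`, never an exception.

## Association models

The three nested multinomial models per parcel pair use a
TD/combined/inattentive outcome (the handful of hyperactive subjects are
excluded, following the outcome set of the reference analysis): Model 1
unadjusted, Model 2 adding the four demographic covariates (age, composite
IQ, gender, handedness), Model 3 adding site. The reference does not state
its three covariate sets; minimal → demographic-adjusted → site-adjusted
is the natural nesting and matches its discussion of site as an
"important" biologically valueless predictor. P-values are
likelihood-ratio tests (deviance difference of nested `nnet::multinom`
fits against $\chi^2_{K-1}$), reported raw — no multiplicity correction,
as in the reference. Degenerate pairs (zero variance) and non-convergent
fits are flagged per cell, not fatal. The 10 binary logistic models use
one pair plus the four demographic covariates; a site-adjusted variant
supports the direction-stability check.

## Numerical and interface choices

* Voxel coordinates are 1-based everywhere, the native R convention;
  NIfTI volumes are written RAS+ with an identity-scaled affine.
* The template is deterministic given the seed: ellipsoidal mask, five
  fixed 8-voxel parcel blocks, central CSF block, one-voxel peripheral
  shell, uniformly sampled seed voxels. Grids too small for any component
  raise a sizing error.
* All randomness flows from `rng_seed`; per-subject scan seeds make
  cohorts and scans bit-identical across runs, and the fast
  connectivity-only generator (`simulate_connectivity_cohort`) replays the
  identical latent draws of the full voxel path.
* Wide-matrix SVDs (leverage scores over thousands of voxels, PCA over
  34,716 seed pairs) are computed from the smaller Gram problem; unit
  tests pin this path to the direct SVD.
* The internal test split defaults to one quarter of the cohort; the
  reference reserved 184 of its 777 training subjects, the same order of
  proportion.

## Problem sizes used by the tests

The suite exercises the pipeline at sizes chosen to make Monte-Carlo bands
meaningful while keeping a full run in minutes: target recovery at 500
subjects per group ($T = 150$, $\pm 0.03$); p-value calibration with 200
null replicates of 300 subjects and power at $n = 600$ (25 seeds,
threshold 0.8); the end-to-end ensemble on 236 subjects over a
$14 \times 14 \times 8$ grid with 80 seeds. The CUR oracle equivalence
sweep covers 100 random matrices up to $12 \times 12$ against a full-SVD
brute force.

## Known limitations

The ensemble's absolute accuracy on synthetic cohorts says nothing about
real-data accuracy; the generator's signal-to-noise is set by its
configuration, not estimated from scans. The seed-connectivity model sees
only weak structure here because non-parcel voxels are spatially
independent by design. Subteam-2-style clustering models are out of scope
and enter only as external prediction sets plugged into the vote. Motion
emulation is a variance model, not rigid-body kinematics, so motion
*correction* methods cannot be meaningfully benchmarked against it — only
motion *detection*, which is what the peripheral-fraction diagnostic
claims.
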