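---
title: "Cross-subject motor imagery decoding with joint spatial-spectral features and instance transfer"
author: "mitransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject motor imagery decoding with joint spatial-spectral features and instance transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two-class motor imagery (MI) decoding asks whether a subject imagined a left-
or right-hand movement from a short window of multi-channel EEG. Two
properties of MI-EEG make this hard in practice: a single subject provides
few labeled trials, and the feature distributions of different subjects
differ substantially (electrode placement, skull geometry, idiosyncratic
rhythm topographies). A classifier trained on a pool of other subjects
("source domain") therefore degrades on a new subject ("target domain") even
though the labeling rule — contralateral attenuation of sensorimotor rhythms
— is shared. This is a covariate-shift setting: the feature distribution
moves between domains while the conditional class structure is preserved.

`mitransfer` implements a complete pipeline for this setting:

1. **Preprocessing** — drop EOG channels, zero-phase band-pass 8–30 Hz
   (the union of the mu, 8–12 Hz, and beta, 13–30 Hz, rhythms), and extract
   the 0.5–3.5 s post-cue window (750 samples at 250 Hz).
2. **Joint features** — common spatial patterns (CSP) variance ratios
   capture the spatial signature of event-related desynchronization (ERD);
   Welch band powers capture its spectral signature; both blocks are
   z-scored with training statistics and concatenated.
3. **Classification with instance transfer** — kernel mean matching (KMM)
   re-weights source trials toward the target feature distribution, and
   those weights initialize a TrAdaBoost ensemble whose final decision is a
   weighted vote over the second half of the boosting iterations.

## Common spatial patterns

For class covariances $H_1, H_2$ (per-trial covariances $XX^\top$
trace-normalized, then averaged within class), CSP whitens the composite
$H_c = H_1 + H_2$ with $R$ satisfying $R H_c R^\top = I$ and
eigendecomposes the whitened class-1 covariance $R H_1 R^\top = Q P Q^\top$.
The filter rows $W = Q^\top R$ diagonalize both class covariances
simultaneously, with eigenvalue pairs summing to one; filters at the extremes
of the spectrum maximize the between-class variance ratio. Features are the
normalized variance shares $f_j = \mathrm{var}(w_j X) / \sum_j
\mathrm{var}(w_j X)$, which sum to one per trial and are invariant to
per-trial gain.

Numerical choices:

* **Whitener.** We use the symmetric inverse square root
  $R = U \Lambda^{-1/2} U^\top$ rather than $\Lambda^{-1/2} U^\top$. Both
  whiten $H_c$, and the retained filters (and hence all features) are
  mathematically identical; the symmetric form is canonical — it returns the
  identity for $H_c = I$ and is insensitive to the arbitrary eigenbasis
  LAPACK selects inside degenerate eigenvalue blocks.
* **Filter count.** Default $m = 6$ for montages of 8 or more channels
  ($m/2$ filters from each end of the spectrum); rank-deficient covariances
  can be diagonally loaded via the `gamma` shrinkage argument.
* **No log transform** is applied to the variance ratios by default (the
  ratios are already normalized and bounded); a `logVariance` switch exists
  in `buildJointFeatures()`.

## Welch band power

Each channel of each epoch is segmented (default: 250-sample, i.e. 1 s,
non-overlapping segments of the 750-sample epoch), each segment is tapered
(Hamming by default) and its periodogram normalized by the window power
$U = \overline{w^2}$ so the white-noise level is taper-independent; the PSD
estimate is the arithmetic mean over segments, trading 1 Hz bin resolution
for a roughly $1/R$ variance reduction. We report one-sided densities, so the
PSD integrates to the signal's mean power (checked against a Parseval
identity in the tests). The spectral feature block is the mean PSD inside
each band — mu (8–12 Hz) and beta (13–30 Hz) by default — per channel,
ordered channel-major. Band-mean aggregation is our documented choice for
turning the spectrum into a fixed-length feature vector; it keeps the block
small (channels × 2) and aligned with the physiological rhythms.

## Kernel mean matching

KMM chooses weights $\beta_i \ge 0$ for the $n$ source trials to minimize
the RKHS distance between the re-weighted source mean embedding and the
target mean embedding,

$$\Big\| \tfrac1n \sum_i \beta_i \Phi(x^s_i) - \tfrac1p \sum_j \Phi(x^t_j) \Big\|^2_{\mathcal H},$$

with a Gaussian kernel $K(x,y) = \exp(-\|x-y\|^2 / 2\sigma^2)$. This is a
quadratic program in $\beta$ (solved with `kernlab::ipop`), under the
standard constraints $0 \le \beta_i \le B$ (default $B = 10$) and
$|\overline{\beta} - 1| \le \varepsilon$ (default $\varepsilon = 0.01$).
A literal $[0, 1]$ box without the mean constraint is available as a preset
(`KernelConfig(B = 1, eps = Inf)`), but note that it can only down-weight
source trials.

Numerical choices:

* **Kernel width.** Median heuristic on the pooled source + target rows by
  default (a fixed `sigma` can be supplied).
* **Ridge.** The unregularized program is degenerate in practice: many
  weightings achieve near-zero discrepancy, and an interior-point solver
  returns an arbitrary one, so pointwise weights were unstable. A diagonal
  ridge on $K$ (default 0.1) selects the smooth representative. Because the
  mean constraint makes uniform weights the minimum-norm feasible point, the
  ridge provably preserves the guarantee that the returned weights achieve a
  discrepancy no worse than uniform weighting — a property asserted in the
  test suite. With the ridge, the weights recover the analytic density ratio
  of a mean-shifted Gaussian with Spearman correlation above 0.9 in the
  package's own checks.
* KMM is computed pooled over both classes (a per-class split is possible by
  calling `solveWeights()` per label subset).

## TrAdaBoost with KMM-seeded initialization

The boosting loop trains a weight-sensitive weak learner on the pooled
source + target-train samples, measures its weighted error $\varepsilon_t$
**on the target training portion only**, and then updates: misclassified
source samples shrink by the fixed Hedge rate
$\beta = 1/(1 + \sqrt{2 \ln n / N})$ (they look unlike the target domain),
while misclassified target samples grow by
$\beta_t^{-1} = (1-\varepsilon_t)/\varepsilon_t$ (AdaBoost-style). The
strong classifier votes with weights $\ln(1/\beta_t)$ over the second half
of iterations, predicting class 1 on ties.

Initialization is either uniform — $1/n$ per source sample, $1/m$ per
target sample, so each domain carries one unit of mass — or KMM-seeded:
the source entries become the KMM weights normalized to unit total mass,
which reproduces the uniform scheme exactly when all KMM weights are equal.

Choices and edge cases:

* **Weak learner.** Default: depth-2 decision tree (`rpart`), honoring
  per-sample weights; `stump` and weighted-`logistic` presets exist. The
  weight contract is probed at fit time on a fixture with conflicting labels
  at duplicated feature locations.
* $\varepsilon_t \ge 0.5$ stops boosting early, keeping completed rounds
  (an under-trained ensemble carries a warning); $\varepsilon_t = 0$ floors
  $\beta_t$ at $10^{-10}$, which makes all such rounds vote with equal
  weight.
* Internally labels are $\{0, 1\}$; the API maps to $\{1, 2\}$
  (left, right).
* With zero source samples the loop reduces to target-only AdaBoost-style
  boosting (verified against a hand-rolled reference).

## Evaluation harness and ablation grid

`runTransferExperiment()` pools all non-target subjects as the source,
splits the target subject's trials into a small stratified training fraction
(default 20%) and a held-out test set, fits every data-dependent step (CSP
filters, standardization statistics, KMM weights, boosting) on source +
target-train only, and scores accuracy
$(TP + TN)/(TP + TN + FP + FN)$ on the target test trials. The test
partition is only ever passed to transform/predict entry points, so leakage
is excluded by construction. `runLoso()` rotates every subject through the
target role.

The classifier modes form the standard ablation grid: `svm` (weight-free
RBF-SVM baseline, $C = 1$, $\gamma = 1/(d \cdot \mathrm{var})$),
`kmm_weighted` (KMM weights fed to a single weight-sensitive classifier —
weighted logistic regression, since "classifying with KMM" requires some
classifier to consume the importance weights), `tradaboost_uniform`, and
`kt_full` (KMM-seeded TrAdaBoost). Feature modes `csp`, `psd` and `joint`
share one code path, so the joint/SVM configuration is exactly the
concatenated-features baseline. Per-block z-scoring with training statistics
precedes concatenation because CSP ratios live in $(0,1)$ while band powers
are unbounded; unstandardized concatenation would let one block dominate.

## The synthetic cohort generator

`generateCohort()` emulates the structure of a multi-subject two-class MI
study: 9 subjects, 72 trials per class (the tests and the acceptance script
use 24–48 trials per class to keep runtimes modest — a package choice,
stated here once), 8 channels at 250 Hz, 3 s epochs. Each channel carries a
mu and a beta oscillation built from three random-frequency, random-phase
sinusoids per band (so band power is analytically known: the band component
has exactly the configured variance, and the ERD attenuation of the mu
amplitude by $1-d$ attenuates mu power by $(1-d)^2$ — the oracle used in the
tests). Class 1 attenuates a fixed channel subset, class 2 a disjoint one.
Trials pass through a per-subject mixing matrix and white noise is added.

The mixing matrix is the product of per-subject log-normal channel gains and
a near-identity orthogonal rotation (re-orthogonalized $I + \sigma E$). The
identity base keeps the ERD topography anchored to fixed channels across
subjects — which both makes the attenuation oracle testable at the channel
level and reflects that real subjects share the gross sensorimotor layout —
while the gain and rotation perturbations produce genuine cross-subject
covariate shift. The gain component matters: purely orthogonal mixing
preserves channel scales and washes out after standardization.

Default levels were calibrated once against the field's operating points and
then frozen: noise SD 4 puts within-subject decodability near 0.9 (clean MI
paradigms decode at 0.8–0.95, not 1.0), and subject-shift SD 0.6 makes the
pooled cross-subject baseline degrade markedly relative to within-subject
performance, the regime instance transfer addresses.

What the generator does **not** emulate: 1/f background spectra, ocular or
muscular artifacts, within-trial nonstationarity, trial-to-trial ERD
latency variability, or volume-conduction correlations beyond the mixing
matrix. Passing tests on this generator therefore demonstrate the
correctness and the qualitative transfer behavior of the pipeline, not
expected accuracy levels on real recordings.

## Known limitations

* Two classes only; no one-vs-rest or joint-diagonalization multi-class CSP,
  and no filter-bank CSP.
* KMM is exact (dense kernel QP), practical to a few thousand source trials;
  no landmark/Nyström approximation.
* The GDF/EDF on-disk formats are not parsed; recordings and epochs
  round-trip through a documented plain-text container
  (`writeEpochSet()` / `readEpochSet()`), and arbitrary arrays can be
  supplied directly through `RawRecording()` / `EpochSet()`.
* Under heavy inter-subject shift the KMM-seeded initialization is close to
  neutral relative to uniform initialization in our synthetic harness: the
  1:1 domain mass split lets the weak learner fit the small target-train set
  almost immediately, so initialization differences decay before the voting
  window. The seeding never required more than the cost of one QP per run.
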