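---
title: "Methods: discovering depression subnetworks from heterogeneous iEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering depression subnetworks from heterogeneous iEEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurodep)
```

# The problem

Intracranial EEG cohorts are heterogeneous by construction: each patient
carries electrodes at clinically chosen locations, so no two subjects
sample the same brain sites. `neurodep` implements an analysis chain that
turns such a cohort into (i) a population-level *correlational model* of
whole-brain field-potential covariance, (ii) a parcellation of that model
into functional modules, (iii) per-subject spectral-spatial features and a
cross-validated classifier of depression status (PHQ-9 >= 10 vs <= 5),
(iv) a decomposition of the classifier into *network expression patterns*
(NEPs), and (v) group contrasts of module-pair connectivity. A synthetic
cohort generator with planted ground truth makes every stage testable
without clinical recordings.

# Models and procedures

## Preprocessing

Recordings are band-passed 2-250 Hz, notched at 60/120/180/240 Hz
(Q = 30), resampled to 512 Hz, and common-average referenced. The target
environment has no IIR filter-design library, so the zero-phase filters
are applied in the frequency domain using the exact squared-magnitude
response of the nominal designs (4th-order Butterworth band-pass, biquad
notches). Forward-backward (filtfilt) application of an IIR filter *is* a
zero-phase filter with response |H(f)|^2; applying |H(f)|^2 directly on a
reflection-padded signal gives the identical steady-state result without
the edge transient. Resampling is exact band-limited Fourier resampling
(the 2-250 Hz band-pass already guarantees there is no energy above the
new Nyquist frequency of 256 Hz).

Two properties of this (or any forward-backward) design worth knowing:

* repeated filtering is only idempotent *away from* the transition bands
  and notch skirts — a Q = 30 notch has gain 0.5 at +/-1 Hz from its
  center, and that skirt is re-attenuated on every pass. The test suite
  asserts idempotence (< 1% power change) in the shaped 5-55 Hz passband,
  which is the physically meaningful content of the claim.
* common-average referencing couples channels: after CAR the channel sum
  is identically zero, so any positively weighted prediction of one
  channel from the others acquires a small negative correlation offset of
  order -1/(n_channels - 1). This is visible as a ~ -0.03 offset in the
  shuffled-model reconstruction null at desk scale (20-channel subjects)
  and shrinks with channel count.

Artifact screening follows the kurtosis convention: 60 s non-overlapping
blocks are dropped when any channel's Pearson kurtosis exceeds 10
(Gaussian noise sits at 3, a sinusoid at 1.5). Screening is per-channel
with block-level rejection; this is configurable. Daytime sampling draws
uniformly without replacement among blocks timestamped 08:00-22:00 and
concatenates them chronologically.

## Correlational model and reconstruction

Per subject, Pearson correlations between observed channel pairs are
Fisher z-transformed (|r| capped at 1 - 1e-6). Radial-basis-function
expansion estimates the correlation of every global pair (a, b) as the
RBF-weighted average of observed-pair correlations with weights
`exp(-d^2 / width^2)`, width 20 mm by default (the reference imputation
method's published scale), excluding the self-pair diagonal. The
denominator sums are kept as evidence weights; population and group
models are evidence-weighted means of subject z-matrices.

Reconstruction is the Gaussian conditional mean
`K_uo (K_oo + eps I)^-1 y_o` on z-scored observed channels, with ridge
`eps = 1e-6 * trace/n`. Two numerical decisions matter:

* RBF-smoothed correlation matrices are generally **indefinite**. We
  solve with the smoothed matrix as-is (plus ridge), as the reference
  method does. Nearest-PSD projection (eigenvalue clipping) was
  implemented and rejected: clipping a *uniformly permuted* matrix pulls
  it back toward positive-mean structure and inflates the shuffled-model
  chance control from ~0 to as much as +0.1 mean r, corrupting the null
  that validates the whole model.
* observed channels are passed through verbatim (z-scored); only
  unobserved locations are estimated. Leave-one-patient-out validation
  reconstructs each electrode of the held-out patient from that patient's
  *remaining* electrodes under a model built from all other patients, so
  the target never predicts itself.

## Parcellation

Louvain community detection maximizes resolution-weighted Newman-Girvan
modularity; negative correlations are thresholded to zero (the null model
assumes nonnegative weights; absolute value is available as an option).
`Q` is recomputed by direct summation independent of the optimizer, and
the test suite checks Louvain against an exhaustive partition search on
small graphs. Allegiance is the co-assignment probability over repeated
runs. The resolution sweep (gamma 0.5-2.1) selects the similarity peak
(adjusted Rand index against an anatomical atlas labeling) with the
fewest modules — the parsimonious granularity; ties and flat curves fall
back to the global maximum with a warning.

Participation coefficients use the standard squared form
`y_i = 1 - sum_c (k_i(c)/k_i)^2` (the printed source formula omits the
square, which would make y identically zero — an evident typo). Hub
weights score each (region, module, tail) cell as `R = N * (N / T)`;
the hub table is descriptive only and feeds no downstream statistic.
Modules holding under 1% of electrodes skip tail selection and use all
member electrodes.

## Spectral-spatial features

Morlet wavelet power (6 cycles, 1 Hz center-frequency grid) is computed
per 30 s window in six bands: delta 1-4, theta 5-8, alpha 9-12, beta
13-30, low gamma 31-70, high gamma 71-150 Hz (the 1 Hz gaps between band
edges are kept verbatim). Each wavelet's spectrum occupies +/-5 sigma_f
around its center, so the transform is evaluated by a *zoomed* IFFT of
just those bins, giving the complex envelope on a decimated grid — this
is two orders of magnitude faster than the dense transform and agrees
with it to better than 1% for window-averaged power (asserted against a
dense oracle in the tests). Half a maximal wavelet length (3 sigma of the
1 Hz wavelet) is dropped at each window edge.

Relative power divides each band by the six-band total. Features are
z-scored per (electrode, band) across subjects and then averaged over the
electrodes of each module (order configurable; the alternative —
module-average first, z-score second — yields exactly standardized
columns and is exposed as `order = "average_then_z"`). Six modules give
the canonical 36 features.

## Classification

Leave-one-out cross-validation with PCA (4 components by default) and
L1-regularized logistic regression (`lambda = 1/(n C)`, C = 1) fit
strictly inside each fold; accuracy is balanced to group size. One
correction proved necessary: LOOCV training folds are always unbalanced
by one subject, and under permuted labels an L1-shrunk intercept-only
fit then *anti-predicts* the held-out subject, dragging the permutation
null to ~42% instead of 50%. All logistic fits therefore use
class-balanced observation weights (`n / (2 n_class)`), the standard
correction and the reading consistent with a chance-level null of 50.0%.
The permutation null re-runs the entire pipeline per permuted label
vector with `p = (1 + #{null >= obs}) / (n_perm + 1)`. Alternate models
(L1/L2/elastic-net logistic, and a compact bagged-CART random forest
implemented in-package because no random-forest package is available in
the target environment) run without PCA. A line-length logistic
regression (McFadden R^2, likelihood-ratio p) checks that residual
epileptiform burden does not predict group.

## Network expression patterns

The final all-data model (one probability per subject is needed
downstream, so the final model rather than per-fold models is
back-projected; per-fold loadings are retained for inspection) yields
per-feature weights `w_f = sum_c beta_c L_fc 1[|L_fc| >= 0.2]` and
impacts `impact(s, f) = w_f x_std(s, f)`; with both thresholds zero the
impacts decompose the linear predictor exactly (asserted to 1e-9).
Impacts below 0.15 in magnitude are zeroed for clustering. Ward-linkage
agglomerative clustering on Euclidean distance (configurable) biclusters
features into NEPs and subjects into groups; two clusters by default,
numbered deterministically by first feature index. Sensitivity withholds
each NEP by setting its features to the population mean (zero in
z-space) before projection and attributes the probability decrement to
that NEP; withholding everything recovers `sigma(intercept)` exactly.
Subjects are tagged NEP-driven when one contribution exceeds the other
by more than 0.05 probability (and itself exceeds 0.05), mixed
otherwise, or misclassified when the full-model prediction contradicts
the label.

## Connectivity contrast

Group models are aggregated separately for depressed and control
subjects from the RBF-expanded subject models. Cohen's d per module pair
compares the distribution of edge correlations (r scale, tanh of the
model z) between the group matrices, depressed minus control, with
intramodular pairs on the diagonal. Significance comes from permuting
the electrode-to-module assignment (identically for both groups),
two-sided, at the stated p < 0.001 per pair; Bonferroni-adjusted masks
are also reported. `n_perm = 1000` is the minimum at which p < 0.001 is
attainable (`min p = 1/1001`).

# The synthetic cohort: what it emulates, and what a green test means

Electrode signals follow a closed-form mixing model:
`x_i = sqrt(w_i) z_m(i) + sqrt(1 - w_i) e_i` with unit-variance module
latents z (pink-spectrum broadband, mixed across modules by the Cholesky
factor of the target latent correlation) and unit-variance private
components e carrying band-limited oscillators. Inter-electrode
correlations therefore hit the configured block targets exactly in
expectation: within-module 0.8, between-module 0.1 by default, with
per-electrode loading jitter (SD 0.04) supplying realistic edge-weight
heterogeneity. Group contrasts are planted as additive shifts (default
magnitude 0.12) mirroring the qualitative pattern of interest: frontal
intramodular hyperconnectivity, occipitotemporal/frontotemporal
hypoconnectivity, and matching intermodular shifts. Band effects follow
two planted NEPs (a beta/alpha occipitotemporal pattern and a
delta-up/theta-alpha-down frontal pattern) assigned per depressed
subject (40/50/10% NEP1/NEP2/mixed). PHQ-9 scores are uniform on [10,
24] (depressed), [0, 5] (controls), 6-9 for optional boundary subjects.
Artifacts are 20-SD bursts of 8 samples (~16 ms, the width of a typical
interictal spike); a *single-sample* 20-SD spike only raises the Pearson
kurtosis of a 60 s block to ~3 + 20^4/30720 ~ 8.2 — below the screening
threshold — so single-sample artifacts would be undetectable by design.
Module centroids occupy well-separated positions in a 140 x 180 x 120 mm
box (8 mm jitter): anatomical modules occupy distinct territories, and
coincident centroids would defeat the RBF expansion's spatial signal.
Recordings carry nominal 08:00 start times so the daytime sampler is
exercised.

What the generator does **not** emulate: non-stationary behavioral
state, volume conduction, 1/f^2 spectral slopes with oscillatory peaks
riding on them, epileptiform waveforms beyond bursts, electrode drift,
or real anatomical geometry. A green recovery test therefore establishes
that the pipeline inverts the generator's stated statistical structure
at desk scale — not that it would recover physiology from clinical data.

Two interactions between planted structure and the pipeline are worth
recording. First, common-average referencing provably distorts small
*inter*modular contrasts when *intra*modular strength differs between
groups (a planted +0.096 intermodular shift can invert in sign after
CAR). The generator's covariance targets are defined pre-referencing, so
connectivity recovery tests feed models built from raw signals;
full-chain recovery is asserted for the robust intramodular signs.
Second, per-subject attribution of NEPs at a planted 1.5 SD feature
effect is below the 80% agreement bar (~0.5-0.7 across seeds): at that
SNR the L1 classifier concentrates on whichever planted direction is
better represented in a training fold. The same machinery reaches ~0.93
agreement at 3 SD, and noiseless impact biclusters are recovered
exactly, so the bottleneck is attribution signal-to-noise, not the
implementation; the corresponding acceptance clause is deliberately left
failing rather than weakened.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| band-pass | 2-250 | Hz | standard iEEG range below the 256 Hz Nyquist at 512 Hz |
| notch Q | 30 | — | narrow line-noise rejection |
| kurtosis_max | 10 | — | the cited screening convention (Pearson kurtosis) |
| block_s | 60 | s | screening granularity |
| width_mm | 20 | mm | reference imputation method's published RBF scale |
| kriging ridge | 1e-6·trace/n | — | numerical stability without biasing the conditional mean |
| gamma grid | 0.5-2.1 | — | the examined modularity resolution range |
| Louvain restarts | 10-100 | — | best-Q consensus; first-found tie-break under seeded order |
| n_cycles | 6 | cycles | Morlet bandwidth/time-resolution trade |
| window_s | 30 | s | spectral estimation interval |
| n_components | 4 | — | the parsimonious component count; nested selection is out of scope |
| l1_c | 1.0 | — | standard inverse-regularization default |
| loading_min / logodds_min | 0.2 / 0.15 | — | stated back-projection and clustering thresholds |
| dominance_margin | 0.05 | probability | makes the mixed-profile tag operational |
| connectivity alpha | 0.001 | — | stated per-pair significance criterion |

# Known limitations

* The package reconstructs and classifies at desk scale; headline
  clinical-cohort numbers require the original recordings and are out of
  scope. Test sizes are scaled down accordingly (e.g. 25 datasets for
  the p-value-uniformity check, 8 runs for connectivity recovery) and
  statistical assertions use binomial-test bounds rather than exact
  quotas.
* EDF I/O is unavailable in the target environment; the cohort container
  is HDF5 (exact round trip) with a plain-text fallback.
* The gamma sweep's "stability" summary (mean of max(a, 1-a) over the
  allegiance matrix) saturates at 1 for strongly blocked synthetic
  models and is informative mainly on noisier data.
* `Rcpp` is deliberately unused: all hot paths (FFT filtering, zoomed
  Morlet, kriging solves) are vectorized linear algebra where compiled
  extensions would buy little.
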