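---
title: "Single-trial FRP classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial FRP classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frptools)
```

## The problem

When a person searches a scene, every fixation delivers a packet of visual
information, and fixations on a sought-for target elicit a positive
fixation-related potential (FRP) in the EEG, akin to the P300 of
stimulus-locked paradigms. `frptools` implements the full analysis needed to
ask whether such FRPs are decodable on a *single-trial* basis from
co-registered eye-tracking and EEG: fixation detection, location labelling,
ocular-artifact removal, fixation-locked epoching, band-pass filtering,
channel concatenation with PCA compression, and shrinkage-regularised Fisher
discriminant analysis (FDA) evaluated by ROC/AUC under several
cross-validation schemes. Because the pipeline targets recordings that users
collect themselves, the package ships a synthetic-data generator that
reproduces the statistical structure every stage assumes, so the whole chain
is testable end to end without any recording.

## The synthetic-data generator

`sim_config()` describes a gaze-contingent visual-search session: twelve
everyday objects on a jittered 4 x 3 grid, one of them the search target.
Each simulated trial visits non-target objects in random order (occasionally
fixating blank background) until the target is found and dwelt upon.

Key defaults, each of them a field a user can override:

* **Gaze**: 120 Hz sampling, 40 px per degree of visual angle (so the 2.5 deg
  labelling radius is about 100 px). Within-fixation jitter is Gaussian with
  0.15 deg SD, far below the detection dispersion; saccades are 30 ms
  constant-velocity sample runs whose samples sit in the middle half of the
  flight path. Re-fixations during the target dwell land on opposite sides of
  the object so that each dwell fixation is separately detectable.
* **Fixation durations**: truncated normal per class, with means (SDs) of
  270 (38) ms for targets, 281 (37) ms for non-targets and 241 (29) ms for
  background fixations — values typical of natural object search. The lower
  truncation equals the 60 ms temporal detection threshold so no generated
  fixation is undetectable by construction.
* **EEG/EOG**: 16 channels (12 EEG, 4 EOG) at 256 Hz, a rate at which an
  800 ms epoch holds exactly `round(0.8 * 256) = 205` samples. Background
  noise is AR(1) with coefficient 0.95 and stationary SD 10 uV per channel —
  spectrally 1/f-like, the dominant character of resting EEG.
* **FRP component**: a Gaussian-windowed positive deflection peaking 400 ms
  after fixation onset with 70 ms temporal SD, projected through a
  parieto-central topography (Pz and Cz largest). The default target
  amplitude is 8 uV — a realistic P300-class effect — with 1 uV for
  non-target and background fixations.
* **Ocular artifacts**: every saccade adds a pulse whose amplitude is
  proportional to the saccade size in degrees, projected mostly onto the EOG
  channels and frontal EEG (gain ~1 uV/deg at Fz, ~10 uV/deg on EOG).

What the generator deliberately does **not** emulate: oculomotor fine
structure (main-sequence kinematics, microsaccades, blinks), volume-conducted
cortical source geometry, latency jitter of the FRP, non-stationary noise,
and inter-subject amplitude variability. Passing tests on this generator
therefore demonstrate that the *pipeline machinery* is correct and calibrated
— recovery of injected effects, chance-level behaviour of nulls, artifact
rejection — not that any particular real dataset is decodable.

### The SNR-to-AUC calibration and the high-SNR reference

Single-trial decodability depends on the amplitude-to-noise ratio, which real
studies cannot dial. We calibrated the generator by running the full
intra-subject pipeline across a target-amplitude ladder of 2, 4, 8 and 16 uV
against the 10 uV noise floor, obtaining mean AUCs of roughly 0.55, 0.61,
0.77 and 0.95. The package's *high-SNR reference configuration* — used where
a test needs reliably strong decoding — is the default configuration with the
target amplitude at the top of that ladder (16 uV). The default itself stays
at the realistic 8 uV.

### Overlap makes "weak" contrasts decodable

A finding worth knowing when interpreting results from this generator (and
from real FRP data): epochs last 800 ms but fixations last ~270 ms, so each
epoch contains the responses of the *following* fixations too. The fixation
immediately preceding the target is (by the search structure) always a
non-target fixation, and the strong target deflection ~700 ms into its epoch
makes non-target epochs partially separable from background epochs even
though their own components are identical (AUC ~0.57-0.62 instead of 0.50).
Saccade-size differences between classes leak additional oculomotor
information through frontal channels. The acceptance check of
"identically generated classes are inseparable" therefore uses a
configuration with equal amplitudes, equal duration distributions and
artifacts off; the strong-target configuration instead checks the qualitative
contrast ordering (target-vs-nontarget far above nontarget-vs-background).

## Fixation detection and labelling

`detect_fixations()` is a dispersion/duration algorithm in the style of
remote-tracker vendor implementations: consecutive valid samples belong to a
fixation while they stay inside a circle with a **diameter** of 2 deg,
anchored at the running centroid (recomputed as samples accrue — the standard
I-DT behaviour; the anchoring rule is a design choice since vendor documents
specify only the circle). Runs shorter than 60 ms are discarded. One isolated
invalid sample inside a run is tolerated; longer dropouts break the run.
Durations are reported as `n_samples / fs_gaze`, so ground-truth comparisons
are exact up to one sample period.

`label_fixations()` assigns `target` / `nontarget` / `background` by testing
the centroid against circular areas with a **radius** of 2.5 deg anchored at
object centers, the nearest center winning in the (geometrically impossible
under the default layout) case of overlap.

## Ocular-artifact removal

`fit_ica()` implements batch natural-gradient Infomax with a logistic
nonlinearity on the whitened 12-channel EEG, learning rate 0.05 annealed by
10 % whenever the update direction swings by more than 60 degrees, with a
random orthogonal initialisation fixed by seed. Components are unit-variance
normalised, ordered by back-projected power and sign-fixed for
reproducibility.

Component selection is automated: `select_artifact_components()` flags
components whose activation correlates with any EOG channel at |r| >= 0.7
(configurable). This replaces visual scalp-map inspection, which cannot run
unattended; correlation with the EOG reference is the most direct automated
criterion for corneo-retinal artifacts. `remove_components()` back-projects
with the flagged components zeroed, leaving EOG channels untouched. The model
is fit once per subject on that subject's (training) recording and applied
frozen — never re-fit on evaluation data.

## Epoching and filtering

Epochs start at the first sample of each fixation and last 800 ms
(`round(0.8 * fs)` samples; 205 at 256 Hz); fixations whose window would run
past the recording end are dropped with a warning. Epochs are then band-pass
filtered at 0.5-10 Hz, zero phase so FRP latencies are preserved.

The filter realisation required care. A 0.5 Hz Butterworth high-pass has pole
time constants of almost a second, and on a 205-sample window forward-backward
filtering leaves large low-frequency ringing (we measured 17-28 % residual of
a 50 Hz stop-band tone with conventional reflection-padded filtfilt). On a
window shorter than one period of the low cutoff, an ideal high-pass can only
remove the drift terms the window can express — its mean and linear ramp — so
`bandpass_epochs()` realises the high-pass side on such windows as
least-squares mean + trend removal, combined with a true zero-phase 4th-order
Butterworth low-pass (steady-state initial conditions, odd-reflection
padding). Longer windows get the true zero-phase high-pass. Both paths are
exactly linear; pass-band (5 Hz) amplitude is preserved within 5 %, a 50 Hz
tone is attenuated by >99 % and DC exactly, measured over the central half of
the window (the outer ~70 ms carry the unavoidable edge effects of any
finite-window filter).

## Features: concatenation and PCA

Per epoch, channel blocks are concatenated in fixed channel order:
12 x 205 = 2460 dimensions for EEG, 820 for EOG, 3280 for all channels.
`fit_pca()` computes the mean-centered eigendecomposition via SVD of the data
matrix (identical mathematics, stable at d = 2460) and keeps the smallest k
whose eigenvalues reach 99.9 % of total variance; on the reference generator
this lands near 190-200 retained dimensions for ~300 epochs. No whitening is
applied. PCA is fit on training folds only and applied frozen to test folds.

## Shrinkage-regularised FDA

With class counts \(N_{C_j}\), class means \(\mu_{C_j}\) and
\(\mu = \tfrac{1}{n_{cls}}\sum_j \mu_{C_j}\) (the average of class means —
note this differs from the pooled sample mean under class imbalance, and is
implemented exactly in this form):

\[
S_b = \sum_j N_{C_j} (\mu_{C_j}-\mu)(\mu_{C_j}-\mu)^\top,\qquad
S_w = \sum_j \sum_{i \in C_j} (x_i-\mu_{C_j})(x_i-\mu_{C_j})^\top .
\]

Sample covariances are ill-conditioned when epochs are scarce relative to
dimensions, so the within-class covariance is replaced everywhere by the
shrinkage estimate

\[
\Sigma^* = \lambda\,\nu I + (1-\lambda)\,\Sigma,\qquad \nu = \mathrm{tr}(\Sigma)/d,
\]

the convex combination with the equal-variance diagonal target. The intensity
\(\lambda\) defaults to the analytic plug-in estimate (ratio of summed
sampling variances of the covariance entries to the summed squared distance
from the target, clipped to [0, 1]), computed without materialising the
third-moment array. Note that for data whose true covariance *is* isotropic
the estimate correctly approaches 1, not 0.

The projection solves \(S_b V = \lambda \Sigma^* V\) (shrinkage in place of
the raw scatter) by Cholesky reduction to a symmetric eigenproblem, keeping
the \(n_{cls}-1\) leading eigenvectors with signs fixed so the
largest-magnitude entry is positive. For two classes this reduces to
\(w \propto \Sigma^{*-1}(\mu_1-\mu_2)\); the bias is the midpoint rule
\(b = -w\cdot(\mu_1+\mu_2)/2\) (the natural choice when no prior calibration
set exists), scores are \(y = x\cdot w + b\) and the class is the sign.
Multi-class predictions assign the nearest projected class mean.

## Evaluation

`roc_auc()` follows a fixed-sweep construction: scores are min-max mapped to
[0, 1] and thresholded at K = 100 equally spaced values; the AUC is the
trapezoidal area under TPR-vs-FPR (with the curve closed at (0, 0); the sweep
itself starts at (1, 1)). The min-max mapping is monotone, so this agrees
with the exact rank-based AUC up to the K-grid discretisation (< 0.01 at
n = 500, verified against the Mann-Whitney statistic). Chance is 0.5 for any
class prior.

Cross-validation: `run_intra_subject()` uses stratified 10-fold CV. Binary
contrasts (`target_vs_rest`, `target_vs_nontarget`, `target_vs_background`,
`nontarget_vs_background`) keep the true class priors and report AUC; the
`three_class` contrast balances classes by seeded down-sampling first and
reports accuracy (chance 1/3). PCA, the shrinkage intensity and the FDA are
all fit per training fold; a deliberate-leakage switch (`leak = TRUE`) exists
purely as a negative control and demonstrably inflates null-data AUC to ~0.95.
`run_inter_subject()` trains on the pooled epochs of all other subjects and
tests on the held-out subject. `paired_ttest()` wraps the two-tailed paired
t-test for condition comparisons, with zero-variance differences handled
explicitly (t = 0, p = 1 for identical samples; t = +/-Inf, p = 0 for a
constant shift).

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which each property is stable:
single subjects of 8-50 trials (roughly 70-450 epochs), three subjects for
the leave-one-subject-out scheme, five- or ten-seed averages where a null or
a monotonicity claim is asserted, and 10 000 samples for pure chance-level
checks. The calibration ladder uses 10-trial subjects across 4 amplitudes.

## Known limitations

* The generator's FRP has fixed latency and topography; real FRPs jitter in
  both, so real-data AUCs will be lower at matched amplitude.
* The automated EOG-correlation rule can miss artifact components that are
  weakly represented in the EOG channels, and can flag genuine frontal
  activity if it is strongly eye-coupled; the threshold is configurable.
* The short-window high-pass realisation removes only mean and ramp; drift
  components between ~0.5 Hz and ~1.25 Hz (one window period) are attenuated
  less than a long-window filter would achieve.
* `classify()` for the multi-class case uses Euclidean distance in the
  discriminant space without class priors; heavily imbalanced multi-class
  problems should balance first (as `run_intra_subject()` does).
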