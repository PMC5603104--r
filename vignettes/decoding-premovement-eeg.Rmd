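---
title: "Decoding grasp kinetics and types from premovement EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding grasp kinetics and types from premovement EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcpDecode)
```

## The problem

Voluntary movement is preceded by a slow negative EEG deflection over the
contralateral sensorimotor cortex, the movement-related cortical potential
(MRCP), and by modulations of the ongoing EEG rhythms. For brain-computer
interfaces in motor rehabilitation it is useful not only to *detect* an
upcoming movement but to *decode* its task parameters - which grasp the user
intends, or how fast and how forcefully they will contract - from the 2 s of
EEG immediately preceding movement onset. `mrcpDecode` implements that
decoding pipeline end to end: preprocessing, the eight physiologically
established features, a u-statistic-ranked wrapper feature selection, linear
classification under three cross-validation regimes, and selection-frequency
feature importance. Because the kind of recordings the pipeline expects are
rarely public, the package also ships a synthetic generator that emulates
cued grasp experiments, so every stage is testable without any data download.

## The pipeline

### Preprocessing

Continuous EEG and EOG are band-pass filtered 0.05-45 Hz with an order-2
Butterworth filter applied forward and backward (zero phase; effective order
4), with odd-reflection padding at both ends. For surrogate-channel analyses
a large Laplacian is computed around C3: `surrogate = C3 - mean(F7, F3, Fz,
T7, Cz, P7, P3, Pz)` with unweighted neighbors. Because both operations are
linear and time-invariant they commute; `preprocessRecording()` applies the
Laplacian first so only one channel needs filtering.

Movement onset of executed trials is detected from the dynamometer force: the
first sample from which *all* values in a 200 ms moving window exceed the
baseline. The baseline statistic is mean + 3 SD of the rest-phase force; the
constant k = 3 is a package default (configurable), chosen so that with the
generator's force noise the false-crossing probability per sample is
negligible while a 20% MVC ramp is crossed within ~40 ms. Imagined trials
produce no force; their epochs are locked to the task onset (cue trigger +
3 s). Epochs cover the half-open window [-2, 0) s relative to onset - exactly
1000 samples at 500 Hz, onset sample excluded, a convention chosen to remove
any ambiguity about the onset sample itself. Epochs whose FP1 peak-peak
amplitude is strictly above 125 uV are rejected (a span of exactly 125 uV is
kept). The per-recording trial log conserves accounting:
kept + rejected_eog + dropped_onset + dropped_edge = number of trials.

### Features

Eight features per channel per epoch, in a fixed order:

* **RP** - mean amplitude over [-2, -0.5) s (readiness potential / early CNV),
* **NS** - mean amplitude over [-0.5, -0.15) s (negative slope / late CNV),
* **PN** - minimum over the whole window (peak negativity / motor potential),
* average PSD in **delta** (0-4), **theta** (4-7), **alpha** (7-15),
  **beta** (15-30) and **gamma** (30-45 Hz).

The PSD is a single full-epoch periodogram with a Hamming taper (0.5 Hz
resolution for a 2 s epoch at 500 Hz). A single segment is deterministic and
keeps the maximum frequency resolution for the 0-4 Hz band, where the MRCP
energy lives; no detrending is applied for the same reason. "Average power"
is the mean over the band's bins; bands are half-open [low, high) except
gamma, whose upper edge is inclusive to match the 45 Hz low-pass, so the
five bands exactly partition the 0-45 Hz bins. The delta band deliberately
includes the 0 Hz bin (the 0.05 Hz high-pass empties it in practice). One
convention consequence worth knowing: the one-sided periodogram does not
double the DC bin, so for white noise the expected delta-band mean is 15/16
of the other bands' - the tests check against that derived value rather than
naive flatness.

Window mean conventions are half-open as well; whether the NS window's
-0.15 s endpoint is inclusive is not determined by the protocol we follow,
and the half-open choice is ours. Peak negativity is searched over the full
2 s window.

### Feature selection

Features are ranked per one-vs-rest problem by a direction-agnostic
Mann-Whitney separability score `max(U, nx*ny - U)` (ties counted 1/2 via
midranks), highest first, ties broken by the stable montage/feature-type
order. The greedy pass initializes with the top-ranked feature and adds each
subsequent feature iff the leave-one-out accuracy of a regularized linear
discriminant on the augmented set *strictly* improves; strictness prevents
unbounded growth under ties ("improved" is read as strict). All features are
evaluated once. The per-class candidate sets are merged and a second greedy
pass runs over the union, ranked by the mean one-vs-rest score across class
problems (a package choice; max-score ranking would be the alternative), with
the inner leave-one-out now scoring multiclass accuracy. The discriminant's
pooled covariance is regularized by epsilon*I with
epsilon = 1e-6 * trace / p so leave-one-out fits on small folds stay
invertible. The PCA alternative projects on the leading principal axes fit on
the training fold only, with the number of components matched per fold to the
size of the SFS-selected set.

### Classification and evaluation

The 3-class grasp task uses the regularized LDA; the 4-class kinetic tasks
use a linear-kernel SVM (cost 1, a documented default - the protocol does not
state one). Features are z-scored per fold with training statistics (SVM
margins are scale-sensitive; LDA is unaffected). Folds are stratified by
default - with 100-160 trials a literal random partition can lose a class
from a training fold; the literal reading remains available via
`stratified = FALSE`, which redraws degenerate partitions. Accuracies are
averaged over the ten folds; the pooled confusion matrix is accumulated from
raw counts and then row-normalized. Leave-one-subject-out (LOSO) training
pools all other subjects' epochs with the full 8-feature surrogate layout and
z-scores with pooled training statistics (whether the original protocol
normalized per subject is not stated; this is our choice).

The theoretical chance level is the smallest accuracy a/n whose one-sided
binomial tail under guessing (p = 1/k) is below alpha = 0.05, capped at 1
when no achievable accuracy is significant. Note that the exact level is not
monotone sample-by-sample in n (e.g. two classes: 0.875 at n = 8 but 0.889 at
n = 9); it decreases on any coarse grid and approaches 1/k.

## The synthetic generator

`generateRecording()` emulates the two study designs: three executed grasp
types (palmar, lateral, pinch; ~5% MVC in 0.5 s; 10-20 montage with 25
channels; 9 s between cues) and four kinetic profiles of an isometric palmar
grasp (0.5 s or 3 s ramps to 20% or 60% MVC, executed or imagined). EEG and
EOG are synthesized at 500 Hz, force at 2000 Hz. Components:

* **MRCP**: a piecewise template - flat baseline, linear negativity from the
  class's onset-of-negativity to 0.7 x amplitude at -0.15 s, a sharper dip
  reaching the full (negative) amplitude exactly at onset, exponential
  rebound. This is the simplest shape reproducing grand-average morphology.
  Imagined-mode recordings reuse the template scaled by 0.4, mirroring the
  smaller imagery amplitudes.
* **Volume conduction**: the class signal is placed on C3 and copied to the
  montage with a Gaussian kernel over schematic 10-20 coordinates
  (sigma = 0.3 head-radius units), which makes channel importance nontrivial.
* **Rhythms**: per band, band-limited Gaussian noise at C3 whose power is
  multiplied by the class's band gain inside each premovement window.
* **Background**: independent 1/f^alpha Gaussian noise per channel
  (alpha = 1, RMS 3 uV) plus white noise (RMS 1 uV).
* **Blinks**: with probability `eogRate` per trial, a 300 ms raised-cosine
  transient (peak 200 uV) lands on FP1 inside the premovement window, with
  attenuated copies on frontal channels - guaranteeing rejection at the
  125 uV threshold.
* **Variability**: per-subject log-normal effects on each class's MRCP
  amplitude and band gains (log-sd `subjectEffectSd`), and per-trial
  log-normal amplitude jitter. The subject effects span the two LOSO
  extremes: log-sd 0 gives fully shared structure, log-sd 2 effectively
  scrambles the class-parameter ordering across subjects.
* The kinetic-task montage is the 20-channel sensorimotor grid extended by
  F7, T7 and P7 so the full Laplacian ring around C3 exists (23 channels);
  the grasp montage has 25 channels.

Single-trial MRCP signal-to-noise in real recordings is not well quantified;
the defaults above are assumptions chosen to look like plausible scalp EEG,
not estimates of any study's SNR. The generator also omits, deliberately:
biophysical forward modeling, eye movements other than blinks, EMG
contamination, non-stationary background, and electrode artifacts. Passing
tests therefore demonstrate that the pipeline recovers the kinds of structure
it assumes - not that real recordings contain that structure at these
magnitudes.

## Study conditions used by the tests and the acceptance script

The heavier checks run at sizes chosen to finish quickly while keeping the
statistics meaningful; they are stated here as the package's own choices:

* *Parameter recovery*: 4 classes x 40 trials, strong class effects (MRCP
  amplitudes -4, -10, -6, -8 uV; alpha gains 1, 2, 0.5, 1.5; beta gains 1,
  0.5, 2, 1.5), surrogate channel, SFS + linear SVM, 10-fold, 5 seeds; the
  mean accuracy must clear the binomial chance bound for 160 test trials.
* *Null calibration*: 20 label permutations per task; mean 10-fold accuracy
  within the binomial 95% band around 1/4 (kinetic) and 1/3 (grasp).
* *Importance*: a grasp run whose class signal lives entirely in the MRCP
  template (identical band gains); the MRCP-component features plus delta
  power must jointly carry the majority of the selection mass.
* *LOSO*: 6 subjects x 40 trials per regime. Shared regime
  (`subjectEffectSd = 0`): accuracy above the chance bound. Idiosyncratic
  regime (`subjectEffectSd = 2`): per-subject accuracies are clustered
  (predictions within a subject share one classifier), so an iid binomial
  band around 1/4 would be invalid; "at chance" is judged by a t-interval
  across subjects.

## Numerical and degenerate-input choices

* Filter padding: odd reflection of length 3 x filter length; the band-pass
  is applied to the continuous recording *before* epoching, so 2 s epochs
  never see edge transients. A 0.05 Hz high-pass settles with a ~3 s time
  constant; recordings shorter than ~10 s are not meaningful inputs.
* Constant feature columns rank last with the minimum separability score
  n^2/2 (ties are stable); constant inputs to the Spearman correlation are an
  error rather than a silent NA.
* A left-out sample whose class would vanish from a leave-one-out training
  set counts as an error rather than aborting the fold.
* `pcaReduce()` silently truncates to the training-data rank (with a
  message) when more components are requested than exist.
* Epochs are cut only when the full window fits in the recording; everything
  else is logged, never imputed.

## Limitations

Accuracies obtained on synthetic data say nothing quantitative about human
EEG: the generator's class effects are dials, not physiology. The pipeline
does not implement ERD/ERS measures, time-frequency feature banks, nonlinear
kernels, or online detection; those are out of scope. The u-statistic
ranking is univariate, so features informative only in combination can be
ranked low and never accepted - an inherent property of the protocol, visible
in the tests only because the generator's class effects are univariate by
construction.
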