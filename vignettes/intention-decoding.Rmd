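---
title: "Methods: synthetic bimodal recordings and intention decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic bimodal recordings and intention decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurointent)
```

## What this package models

`neurointent` implements an end-to-end analysis of simultaneous EEG and
fNIRS recordings of an action-observation experiment with three observed
intentions — grasping a cup to drink (`Sd`), grasping it to move it
(`Sm`), and touching it with unclear intent (`Su`) — and, because no such
dataset is publicly deposited, a synthetic-data generator that emulates the
paradigm with known ground truth.  Every analysis stage can therefore be
validated against planted quantities: evoked amplitudes, hemodynamic peak
times, a neurovascular lag, and condition-specific network structure.

The paradigm is 3 conditions x 7 cup colors x 4 repetitions = 84 trials in
4 sessions of 21, each trial 6 s fixation + 0.5 s cue + 3.5 s observation +
6 s rest, with 2 min between sessions (28.4 min total).  Observation onset
is time zero.  EEG: 64 channels at 1,000 Hz plus two bipolar EOG
derivations.  fNIRS: 48 channels over the bilateral parietal areas, three
wavelengths (780/805/830 nm), 27 ms sampling interval.

## The synthetic generator

**EEG.**  Background activity is spatially mixed 1/f noise (default
amplitude 5 uV, spatial mixing fraction 0.3), a posterior-dominant ~10 Hz
rhythm whose phase diffuses with a coherence time of about a second
(2 uV), and white sensor noise (1 uV).  Each trial adds (a) a cue-locked
negative deflection 500 ms before observation onset on posterior channels
(-5 uV), emulating the visual response to the cue; (b) a multi-lobe evoked
complex on 43 "responsive" channels whose late positive component spans
350-400 ms and scales with condition (defaults 8/5/2 uV for Sd/Sm/Su);
and (c) shared latent signals during the 0-3.5 s observation window that
induce condition-specific inter-channel correlation (see *Planted network
structure*).  Ocular activity is modeled as Poisson blink transients whose
source leaks into frontal channels through a fixed linear mixing; the
recorded EOG carries additional sensor noise.

The evoked complex is deliberately *multi-lobed* (C1/P1-N1-P2-N2 lobes at
irregular latencies before the late component): real visual evoked
responses have this morphology, and it gives the waveform a sharp
autocorrelation, which is what makes the neurovascular lag identifiable
from windowed correlations (a single smooth bump matches too many
alternative alignments).

**fNIRS.**  Each trial's oxyhemoglobin course is a boxcar of neural
activity over the observation period, shifted by the neurovascular lag
(default 1,700 ms) and convolved with a double-gamma kernel whose
zero-crossing is calibrated so the response peaks exactly at the requested
post-onset time (default 3 s) — while the boxcar is still on, the
convolution peaks where the kernel crosses zero, so the calibration is
exact rather than fitted.  Response amplitude is condition ordered
(defaults 0.05/0.035/0.02 mM*mm) with left-hemisphere lateralization and a
smooth spatial gain over each optode patch.  A lag-shifted copy of the
evoked complex (0.02 mM*mm, equal in every condition) carries the
neurovascular coupling; its equal amplitude reflects the observation the
analysis is designed to reproduce — high ERP-HbO correlation in *all
three* conditions (windowed Pearson correlation is scale invariant, so the
condition ordering lives in the response amplitude instead).
Deoxyhemoglobin is `-1/3` times HbO, a common empirical ratio.
Physiological noise: a ~0.1 Hz Mayer wave, ~1 Hz cardiac pulsation,
random-walk drift, and white noise (0.008/0.005/0.004/0.003 mM*mm).  The
concentrations are converted to strictly positive three-wavelength light
intensities by the forward Beer-Lambert model, the exact inverse of
`mbll_convert()`, so the instrument-level data format is raw intensities.

**Planted network structure.**  During each observation window, channels
receive shared latent signals according to a condition-dependent community
map, with condition-dependent per-channel participation weights (1 vs
0.25).  Both layers matter: a relabeled partition alone produces
isomorphic graphs, which nodal metrics cannot distinguish, so the
participation weights are what make the planted differences visible to
per-node statistics.  The two modalities are complementary by design: EEG
separates `Sd` from the other two conditions; fNIRS (whose latent signals
are slow, vasomotion-band half-sine and ramp shapes, so they survive the
0.01-0.1 Hz analysis filter) separates `Su`.  Neither modality alone can
resolve all three intentions from network topology; their fusion can —
which is exactly the qualitative pattern the decoding analysis should
reproduce (fused > EEG > fNIRS).

With `effect_size = 0` all condition-dependent quantities collapse to a
common value (amplitudes, maps, weights), giving exchangeable null data
for type-I-error checks.

**What the generator does not emulate:** photon transport or optode
forward models, motion artifacts, channel-quality differences,
subject-level anatomical variability, and source-space structure.  Passing
tests on synthetic data therefore demonstrate correctness of the analysis
chain and recoverability of planted effects under realistic noise — not
performance on any particular real dataset.

## Preprocessing

EEG: 50 Hz notch (second-order zero-phase band-stop, configurable),
1-30 Hz fourth-order zero-phase Butterworth band-pass, regression-based
EOG removal, epoching to (-0.7, 3.5) s, baseline correction over
(-0.7, -0.5) s.  fNIRS: modified Beer-Lambert conversion (least-squares
solution of the 3-wavelength x 2-chromophore system; extinction
coefficients and DPF shipped as documented constants), 0.01-0.1 Hz
second-order zero-phase band-pass, epoching to (-6.5, 5.5) s, baseline
correction over (-6.5, -0.5) s.

Zero-phase (forward-backward) filtering is used throughout so filtering
cannot shift the 350-400 ms window.  The fNIRS band-pass uses order 2
because at a 37 Hz sampling rate the normalized band edges are ~1e-3 and
higher-order transfer-function polynomials become numerically
ill-conditioned.  Epochs are endpoint-inclusive on the sampling grid:
`floor(span * rate) + 1` samples, e.g. 4,201 EEG samples for (-0.7, 3.5) s
at 1 kHz and `floor(12.0 / 0.027) + 1 = 445` fNIRS samples.

Artifact removal is regression on the (centered) EOG channels rather than
ICA: with the generator's linear leakage model regression is exactly
identifiable and deterministic, whereas ICA depends on the algorithm,
seed, and component-selection heuristics.

**Band choices per analysis.**  The 0.01-0.1 Hz band is used for the
waveform, ANOVA and block-t-test analyses.  The neurovascular-coupling lag
analysis instead uses the unfiltered (full-bandwidth) HbO epochs: the lag
is resolved from sub-100-ms structure that a 0.1 Hz low-pass removes by
construction.  The per-trial network analysis uses the narrow-band epochs,
matching the waveform analyses; this is why the planted fNIRS connectivity
signal is placed in the vasomotion band.

## Sensor statistics

Per channel, the trial-wise mean amplitude in an analysis window
(350-400 ms for ERPs at alpha = 0.001; 0-3.5 s for HbO at alpha = 0.05) is
submitted to a one-way ANOVA across conditions with pooled-SD pairwise
post hoc tests, Bonferroni corrected (`p_corr = min(1, 3 p_raw)`).  No
correction across channels is applied (per-channel testing convention).
HbO observation-vs-baseline contrasts are paired t-tests of the mean over
`[t - 0.5, t + 0.5]` s (t = 1..5 s) against the mean over the
-6.5..-0.5 s baseline block.  Topographic maps use exact thin-plate-spline
interpolation (exact at channel sites, reproduces affine fields), masked
to the convex hull of the montage.

## Neurovascular lag surface

Grand-averaged ERP and HbO waveforms are reduced to one waveform per
condition by a cross-channel mean.  For window lengths X = 100..600 ms
(1 ms steps) and lags Y = 0..3,000 ms (27 ms steps), the Pearson
correlation between ERP `[0, X]` and HbO `[Y, Y + X]` (HbO linearly
interpolated to the 1 ms grid) is computed per condition; the analysis
reports the region where the minimum over conditions exceeds 0.8 and the
peak of that minimum surface (ties break toward the smallest Y, then the
smallest X).  Zero-variance segments are recorded as missing and excluded.
The implementation uses prefix sums for speed and is tested against a
two-pass textbook Pearson oracle at 1e-12.

## Networks and nodal features

Per trial, the 0-3.5 s window yields a channel x channel Pearson
correlation matrix, normalized to Fisher Z (`atanh`, |r| clipped at
1 - 1e-7, zero diagonal).  A binary graph retains the strongest 30 % of
|Z| edges (proportional threshold; ties break by |Z| then node-pair order,
so the graph is reproducible).  The binary convention is used because the
five nodal metrics are implemented in their standard binary forms: degree,
clustering coefficient, betweenness centrality (Brandes accumulation,
normalized by `(n-1)(n-2)/2`, disconnected pairs contribute 0),
eigenvector centrality (principal eigenvector of the largest connected
component, unit Euclidean norm, 0 elsewhere, 0 for edgeless graphs), and
local efficiency (global efficiency of each node's neighbor subgraph).
All five are validated against brute-force enumeration oracles on random
graphs and against igraph.

## Classification

Features are the per-trial nodal metrics (64 x 5 = 320 EEG columns,
48 x 5 = 240 fNIRS columns, 560 fused).  Decoding uses 10-fold stratified
cross-validation repeated 10 times; with 84 trials each fold trains on ~25
and tests on ~3 trials per condition.  Everything is fit inside the
training folds: per-column z-scoring, Relief-F ranking (k = 10 nearest
hits/misses, Manhattan distance on min-max-normalized features, all
training instances used), and an RBF-kernel C-SVC (libsvm via e1071) whose
`(C, gamma)` are chosen by nested stratified inner cross-validation over a
powers-of-two grid (ties toward the smallest C, then gamma).  A "pooled"
compatibility mode tunes once on the full data instead; it is
optimistically biased and off by default.

Feature count after Relief-F: 60 for single-modality tables.  For the
fused table the default is 140 (~25 % of 560): with a fixed budget of 60,
the individually stronger EEG features crowd out the fNIRS features
entirely and fusion degenerates to EEG-only decoding; the larger budget
lets both modalities contribute.  This is the one place the package
deviates from a fixed-60 default, and it is set per call, not hidden.

## Problem sizes used by the automated checks

The validation suite keeps the generator's scientific defaults (84 trials,
16 s trials, condition effects as above) but scales computational knobs
chosen for iteration speed, and documents them here as package choices:
lag-recovery checks run the full 84-trial paradigm with EEG synthesized
at 125 Hz (the lag analysis interpolates to a 1 ms grid either way and
the 1-30 Hz band is preserved below that Nyquist); cohort-level decoding
checks use 42-trial subjects (2 repetitions per cell) at the same reduced
rate, a reduced 2 x 3 SVM grid with 3-fold inner tuning, and 2
repetitions of the outer cross-validation (the chance-level null check
keeps the full 10 x 10); type-I checks simulate 500 null channels
directly at the epoch level.  None of these change the planted effect
sizes or noise levels.

The chance-level check runs on a null subject (`effect_size = 0`) with
permuted labels.  On a subject with planted structure, a fixed label
permutation drives cross-validated accuracy systematically *below* chance
— with clustered features, the permuted labels of a test trial's cluster
mates are anti-correlated with its own, a known pathology of permutation
nulls — whereas information leakage would push accuracy above chance.
Null data isolate the leakage question, and there the binomial interval
around 1/3 applies.

## Numerical choices and degenerate inputs

- Fisher-Z clipping at |r| = 1 - 1e-7 bounds Z at ~8.1 for duplicated
  channels; constant channels get zero-weight edges plus a diagnostic.
- Correlation prefix sums guard against cancellation with a relative
  variance floor (1e-12 of the sum of squares); flagged cells are treated
  as missing.
- The double-gamma zero crossing is solved by `uniroot` at 1e-12 and the
  response template is integrated on a 5 ms grid, so planted peak times
  are exact to that grid.
- Proportional thresholding and Relief-F rankings break ties
  deterministically (stable orders), making every pipeline stage
  reproducible bit-for-bit under a fixed seed.
- Baseline windows outside an epoch, non-positive intensities (named by
  channel and sample), collinear layouts, single-class training sets, and
  unstratifiable label sets raise errors rather than propagating NaN.

## Known limitations

Condition effects enter the generator additively with stationary noise;
real data have trial-to-trial latency jitter, non-stationary artifacts,
and subject variability that are not modeled.  The decoding accuracies on
synthetic cohorts are therefore not predictions of real-world accuracy —
only the qualitative modality ordering and the correctness of the
machinery are claimed.  Source-space localization (sLORETA and kin) is
out of scope, as are EDF/SNIRF adapters (the native interchange format is
plain TSV + JSON).
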