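# neurointent

Simulation and analysis of simultaneous EEG-fNIRS recordings of an
action-observation experiment, ending in three-class decoding of the
observed intention from complex brain-network features.

## The problem

When people watch someone interact with an object, their brain activity
differs with the actor's apparent intention.  In the paradigm this package
models, participants watch a hand interact with a cup under three
conditions — grasping it to drink (`Sd`), grasping it to move it (`Sm`),
and touching it with unclear intent (`Su`) — while 64-channel EEG
(1,000 Hz) and 48-channel fNIRS (780/805/830 nm, 27 ms sampling) are
recorded together.  The analysis questions are: do the evoked electrical
(350-400 ms) and hemodynamic (~3 s) responses order with intention
clarity; how far does the hemodynamic signal lag the electrical one
(neurovascular coupling); and can the three intentions be decoded from
per-trial functional connectivity networks?

Since no such dataset is publicly deposited, the package includes a
first-class synthetic-data generator with known ground truth (planted
amplitudes, peak times, a neurovascular lag, and condition-specific
network structure), so every stage of the analysis is testable against
planted answers.

## The method

- **Preprocessing** — zero-phase band-pass (EEG 1-30 Hz, fNIRS
  0.01-0.1 Hz) and notch filtering; regression-based ocular artifact
  removal; the modified Beer-Lambert law
  `dOD(lambda, t) = sum_i eps_i(lambda) DPF(lambda) dC_i(t) / 10`
  solved by least squares for dHbO and dHbR per time point; epoching to
  observation onset and baseline correction.
- **Sensor statistics** — per-channel one-way ANOVA of window means
  across conditions with Bonferroni post hoc tests; paired
  observation-vs-baseline t-tests of HbO from 1 to 5 s; thin-plate-spline
  topographic maps.
- **Neurovascular coupling** — Pearson correlation between the
  grand-averaged ERP segment `[0, X]` ms and the HbO segment
  `[Y, Y + X]` ms for X = 100..600 ms and Y = 0..3,000 ms; the region
  where the minimum over conditions exceeds r = 0.8 localizes the lag.
- **Networks** — per trial, channel-wise Pearson correlations over the
  0-3.5 s observation window, Fisher-Z transformed and proportionally
  thresholded (density 0.3); five nodal metrics per channel: degree,
  clustering coefficient, betweenness centrality, eigenvector centrality,
  local efficiency.
- **Decoding** — Relief-F feature ranking (k = 10) and an RBF-kernel
  C-SVC with grid-searched `(C, gamma)`, evaluated by 10-times-repeated
  stratified 10-fold cross-validation with all fitting inside the
  training folds; EEG, fNIRS and fused (560-feature) variants.

## Worked example

```r
library(neurointent)

# one reduced synthetic subject (12 trials, EEG at 250 Hz for speed)
cfg <- paradigm_config(n_colors = 2, n_reps = 2, n_sessions = 1,
                       eeg_rate_hz = 250, seed = 3)
rec <- generate_subject(cfg, ground_truth(), seed = 11)
rec
#> <raw_recording> 12 trials; EEG 64 ch x 48000 samples @ 250 Hz; ...

eps <- preprocess_subject(rec)
eps$hbo
#> <epoch_set> HbO: 12 trials x 48 channels x 445 samples @ 37.04 Hz
#>   window [-6.507, 5.481] s; conditions: Sd=4 Sm=4 Su=4

# the planted oxyhemoglobin response peaks near 3 s after onset
ga <- grand_average(eps$hbo)
wave <- summary_waveform(ga)
attr(ga, "times_s")[apply(wave, 1, which.max)]
#> [1] 4.239 3.942 3.969   # narrow-band filtered; the clean peak is at 3 s

# full-schedule arithmetic
sch <- build_schedule(paradigm_config())
nrow(sch); attr(sch, "total_duration_s") / 60
#> [1] 84
#> [1] 28.4
visual_angle(28, 80)
#> [1] 19.85034
```

The numbers printed above are what the code produces: 84 trials lasting
28.4 min, a 19.85 degree horizontal visual angle, and HbO waveforms whose
narrow-band-filtered peak sits just after the planted 3 s (the 0.01-0.1 Hz
filter smears the clean peak; the noise-free recovery tests hit 3 s to one
sample).

An end-to-end run (simulation through decoding, with on-disk artifacts
and a provenance record) is one call:

```r
res <- run_pipeline(run_config(
  paradigm = list(n_reps = 2, n_sessions = 2, eeg_rate_hz = 250),
  classification = list(n_reps = 2, C_grid = 2^c(0, 4),
                        gamma_grid = 2^c(-7, -4, -1), inner_folds = 3),
  seed = 1, out = "run1"))
res$accuracy_table
#>   modality  accuracy  sd_folds
#> 1      eeg 0.6904762 0.2260453
#> 2    fnirs 0.4761905 0.2675151
#> 3    fused 0.7738095 0.1699243
res$nvc_peak$peak_Y_ms   # planted neurovascular lag: 1700 ms
#> [1] 1701
```

On synthetic cohorts the decoders reproduce the qualitative modality
ordering the method is designed to show: fused > EEG > fNIRS, with every
modality above the 1/3 chance level.

A thin CLI wrapper is included at `inst/cli/neurointent`
(`neurointent run --config cfg.yaml --seed 1 --out dir/`).

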