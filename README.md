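# kmibci

Does a motor-imagery questionnaire predict brain-computer interface (BCI)
performance? `kmibci` implements the full analysis chain needed to study
that question on simulated cohorts: a synthetic EEG generator with
controlled event-related desynchronization (ERD), preprocessing and
epoching, four motor-imagery-vs-rest classifiers built on the Riemannian
geometry of covariance matrices, the questionnaire/statistics battery, and
event-related spectral perturbation (ERSP) group analysis with permutation
FDR.

It is aimed at BCI methodologists who want a reproducible, fully synthetic
testbed for questionnaire-performance studies — where the ground truth
(each subject's ERD depth, and the latent correlation between covariates
and ERD) is known by construction, so both null and positive findings can
be planted and recovered.

## The model in brief

* **Protocol.** Per trial: 6 s rest (red cue), 2 s warning (orange), 4 s of
  right-hand kinesthetic motor imagery (green), ~2 s jittered inter-trial
  interval; 40 trials per session, 256 Hz, 32-channel 10-20 montage + EMG.
* **Signal.** Per channel: 1/f background + common mode, band-limited mu
  (10 Hz) and beta (20 Hz) oscillators. During imagery the oscillator
  envelope at channel *c* is scaled by `1 − depth·w_c` (`w` a fixed gain
  map peaking at C3); after imagery the beta envelope is scaled by
  `1 + rebound·w_c` for 1 s.
* **Features.** 3.5-s epochs (`T = 896` samples): one imagery epoch 0.5 s
  after the green cue, one rest epoch 2.5 s after the red cue; per-epoch
  spatial covariance `Σᵢ = XᵢXᵢᵀ/(T−1)` (32×32, SPD).
* **Classifiers.** CSP+LDA (8 log-variance features), MDRM (minimum AIRM
  distance to class Fréchet means), gfMDRM (tangent-space Fisher filtering
  before MDRM) and TS+LR (tangent-space projection at the training Fréchet
  mean, 528-dimensional isometric vectorisation, ridge logistic
  regression), all under stratified 4-fold cross-validation.
* **Statistics.** MIQ-RS scores `(mean(items) − 1)/6 × 100`; K+/V+ groups
  at score ≥ 70, Perf± at the cohort mean, Manual± at weekly-or-daily
  practice; Pearson/Spearman correlations, Welch's t, Mann-Whitney U,
  Glass's Δ (larger sample as control), Shapiro-Wilk, Benjamini-Hochberg
  FDR at q = 0.20.
* **ERSP.** Sliding Hanning 256-point FFT (hop 32), dB change
  `10·log₁₀(P(f,t)/P̄_baseline(f))` against a 2-s baseline ending 2 s before
  imagery onset; per-cell permutation test between groups with BH-FDR at
  0.05.

## Worked example

```r
library(kmibci)

cfg <- sim_config(n_subjects = 1, n_trials = 40, seed = 7)
set.seed(7)
profile <- generate_profile(cfg)     # ground-truth ERD depth, answers, factors
session <- generate_session(profile, cfg)
epochs  <- extract_epochs(bandpass(session))
epochs
#> <epoch_set> 80 trials (KMI:40, REST:40) x 32 channels x 896 samples @ 256 Hz

crossval_accuracy(epochs, "tslr", k = 4)$mean    # decoding accuracy, one subject
```

The `analysis/` directory holds the full workflow as numbered drivers
(simulate → preprocess → classify → stats → ERSP), configured by
`analysis/config.yaml` (12 subjects, latent manual-activity correlation
0.6 by default):

```sh
Rscript analysis/01_simulate.R     # EDF sessions + subjects.csv + ground truth
Rscript analysis/02_preprocess.R   # band-pass + epochs
Rscript analysis/03_classify.R     # 4 methods x 4-fold CV per subject
Rscript analysis/04_stats.R        # scores, groups, correlations, group tests
Rscript analysis/05_ersp.R         # C3 ERSP maps + Manual+/- permutation test
```

With the shipped configuration this prints, among other things:

```
Cohort mean accuracy by method:
   method mean_accuracy
1 csp_lda     0.9479167
2  gfmdrm     0.9468750
3    mdrm     0.9447917
4    tslr     0.9489583

 method     variable    type estimate p_value  n significant
   tslr  freq_manual pearson  0.54358  0.0677 12       FALSE

Manual+ (n=6): mean mu-band ERSP 0-2 s = -4.03 dB
Manual- (n=6): mean mu-band ERSP 0-2 s = -2.34 dB
```

Read: decoding is accurate across methods (simulated signals carry no
artifacts, so accuracies run higher than in human cohorts); the planted
latent correlation of 0.6 between manual-activity frequency and ERD depth
surfaces as an estimated Pearson r ≈ 0.54 against decoding accuracy (not
significant at n = 12 after FDR — recovering it reliably needs cohort-scale
n, as the calibration tests show at n = 35); and the Manual+ group shows
the stronger mu-band desynchronization (more negative dB) during imagery.
All tables land under `results/`.

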