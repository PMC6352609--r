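---
title: "Simulating and analysing kinesthetic motor-imagery BCI experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing kinesthetic motor-imagery BCI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

A recurring question in brain-computer interface (BCI) research is whether a
subject's ability to control a motor-imagery BCI can be predicted from a
questionnaire — in particular the MIQ-RS, whose 14 items (7 kinesthetic, 7
visual, each rated 1-7) measure self-perceived motor-imagery quality. The
analysis chain implemented here asks that question end to end: simulate a
cohort of subjects performing right-hand kinesthetic motor imagery (KMI),
decode imagery versus rest from each subject's EEG with four standard
classifiers, and correlate decoding accuracy with questionnaire scores and
personal factors such as the declared frequency of manual activities (FMA).

Because no public recording of this protocol exists, the package's simulator
is a first-class, tested component: it produces cohorts with *known*
ground-truth effect sizes, so every downstream stage can be validated — the
null scenario (questionnaire unrelated to performance) and the positive
scenario (FMA correlated with performance) are both recoverable by
configuration.

## The simulator

Each trial follows the protocol: 6 s rest (red cue), 2 s warning (orange),
4 s of KMI (green), then an inter-trial interval drawn uniformly from
1.5-2.5 s ("around 2 s"). A session has 40 trials by default; sampling is at
256 Hz over a 32-channel 10-20 montage covering premotor, motor,
somatosensory and occipital sites, plus one near-silent EMG channel (the
protocol requires imagery without movement).

Per channel the signal is a sum of:

* **1/f background noise** (10 µV RMS by default), synthesised spectrally,
  plus a shared common-mode component at 20% amplitude so that spatial
  covariance matrices are full-rank but not diagonal;
* **a mu oscillator** (10 Hz, 6 µV at the gain-map peak) and **a beta
  oscillator** (20 Hz, 4 µV), each a common band-limited source projected to
  all channels plus 30% independent per-channel narrowband activity;
* **event-related modulation**: during each green interval the oscillator
  envelopes at channel *c* are multiplied by `1 - depth * w_c`, where `w_c`
  is a fixed Gaussian gain map centred on C3 (contralateral hand area,
  `w_C3 = 1`); for 1 s after imagery offset the beta envelope is multiplied
  by `1 + rebound * w_c` (the post-imagery beta rebound).

`erd_mu_depth`, `erd_beta_depth` (fractions in [0, 1]) and `rebound_gain`
are per-subject ground truth, drawn from Beta(2, 2) and Beta(2, 4) by
default — a realistic mid-spread population with neither floor nor ceiling
pile-up. Trial-to-trial ERD depth jitters multiplicatively with SD 10%;
inter-trial ERD variability is not reported in the literature this design
follows, so that value is a free parameter, not an empirical one.

Questionnaire answers and personal factors are tied to the ERD-depth latent
through a Gaussian copula: each covariate with declared latent correlation
`c` is generated from a latent `z = c*z0 + sqrt(1-c^2)*e` and then
discretised to its Likert range (1-7 for MIQ-RS items, 0-5 for frequency
ratings). Discretisation attenuates the observed correlation below `c`,
which is the realistic behaviour for Likert data. The default scenario has
zero latent correlation for the MIQ-RS items (the null finding) and for all
factors; scenarios with a positive FMA-performance association set
`covariate_corr = list(manual = 0.6)`. Cohort demographics default to the
studied population (age 25.8 ± 10.4, 13/35 female, 3.3 ± 3.1 years of
post-secondary education).

**What the simulator does not emulate:** no forward head model (the gain map
is a fixed topography), no ocular/movement artifacts, no non-stationarity of
the background beyond the cue-locked modulation, and no visual-imagery
specific dynamics. Passing tests therefore demonstrate correctness of the
analysis chain under controlled ERD structure, not robustness to real-world
artifacts — and because simulated signals are artifact-free, decoding
accuracy at mid-range ERD depths runs higher than typical human cohorts
(where the cohort mean sits nearer 80%).

## Preprocessing

The continuous recording is band-passed 8-30 Hz with a 5th-order Butterworth
filter. The filter is applied zero-phase (forward-backward) since the
analysis is offline — the effective magnitude response is the squared
Butterworth response; filtering precedes epoching so transients stay outside
the epochs. The EMG channel passes through untouched.

Epochs last 3.5 s (`T = round(3.5 * fs)` = 896 samples at 256 Hz): one
kinesthetic epoch per green cue starting 0.5 s after it, one rest epoch per
red cue starting 2.5 s after it — 40 + 40 = 80 trials per session. Sample
windows are half-open with floor rounding, `[floor(t*fs), floor(t*fs) + T)`,
so every epoch has exactly `T` samples regardless of the fractional onset.
An epoch running past the end of the recording drops that trial with a
warning.

## Classifiers

All four methods operate per subject under stratified 4-fold
cross-validation (shuffle seed 42 by default; a chronological fold option
exists since the original fold ordering is not documented). Everything —
spatial filters, means, classifiers — is fitted inside training folds only.

The feature object for the Riemannian methods is the sample spatial
covariance of each centred epoch, `Sigma_i = X_i X_i' / (T - 1)`, a
symmetric positive-definite (SPD) 32x32 matrix. SPD matrices are treated
under the affine-invariant Riemannian metric (AIRM),
`delta(A, B) = ||log(A^{-1/2} B A^{-1/2})||_F`, which is invariant under any
linear mixing of the channels.

* **CSP+LDA** — common spatial patterns from the generalised eigenproblem
  `S1 w = lambda (S1 + S2) w` on the class-average covariances; the first
  and last 4 filters are kept (F = 8), features are the log-variances of the
  filtered epoch, and a Fisher LDA with equal priors classifies them.
  Eigenvalue ties break by the dominant-coefficient channel index, for
  determinism.
* **MDRM** — each class summarised by the Fréchet (Karcher) mean of its
  training covariances; a trial goes to the nearer class mean in AIRM
  distance, ties to the first class in label order.
* **gfMDRM** — geodesic filtering before MDRM. The published description is
  only "a generalisation of LDA to the manifold", so the package concretises
  it as tangent-space Fisher filtering: map training matrices to the tangent
  space at their global Fréchet mean, fit a Fisher discriminant subspace
  (dimension 1 for two classes), orthogonally project tangent vectors onto
  it, retract to the manifold. With full dimension the filter is the
  identity. One caveat found empirically: under *isotropic* tangent nuisance
  noise the filter is neutral at best, because the MDRM distance difference
  already projects onto the mean-difference axis — the filter genuinely
  helps when nuisance variation is concentrated along non-discriminant
  directions, which is the construction the test suite uses.
* **TS+LR** — covariances projected to the tangent space at the Fréchet
  mean of the training set (the point where the tangent space approximates
  the manifold best), vectorised isometrically (upper triangle, off-diagonal
  x sqrt(2); length C(C+1)/2 = 528), and classified with an L2-regularised
  logistic regression (ridge penalty 1/n). The published label "Linear
  Regression classifier" is read as the tangent-space literature's standard
  regularised linear model; a literal least-squares variant with a 0.5
  threshold is available via `classifier = "ols"` for comparison.

Numerical choices: the Karcher iteration initialises at the arithmetic mean
with unit step, tolerance 1e-8 on the gradient norm, at most 50 iterations
(non-convergence is an error, not a silent result). Covariances are
regularised by `eps * I`, `eps = 1e-10 * trace/C`, only when the smallest
eigenvalue is non-positive. Matrix log/exp go through eigendecomposition of
the symmetrised argument.

## Questionnaire scoring and statistics

MIQ-RS scores rescale item means from the 1-7 answer range to 0-100:
`score = (mean - 1)/6 * 100`. Which items are "hand-related" is not
standardised, so subset scores take configurable item-index lists (defaults
`hand = {2, 4, 6}`, `arm = {1, 2, 4, 6, 7}` within each scale — explicitly
non-authoritative).

Group assignments: K+/V+ at score >= 70 (a common cut-off for
perceived-quality questionnaires); Perf+ strictly above the cohort mean
accuracy; Manual+ at weekly-or-daily manual activity (ordinal ratings
0 = never ... 4 = daily, 5 = several times daily).

The inferential battery uses two-sided tests throughout: Pearson and
Spearman correlations (t approximation), Welch's t with Satterthwaite
degrees of freedom, Mann-Whitney U (exact enumeration when both groups have
<= 8 observations and no ties; normal approximation with tie correction
otherwise), Shapiro-Wilk normality checks, and Glass's Delta with the larger
sample as control (its SD is the denominator — appropriate when variances
cannot be assumed equal). Multiple comparisons are controlled with the
Benjamini-Hochberg step-up procedure at q = 0.20 per declared test family
(by default one family per classifier and correlation type); the realised
threshold `k*q/m` is reported rather than a hard-coded adjusted alpha.

## ERSP time-frequency analysis

Event-related spectral perturbation maps use a sliding Hanning-tapered
256-point FFT with a 32-sample hop (taper and hop are not documented in the
original description; they are fixed here for determinism). Power is
averaged over trials and expressed as `10*log10(P(f,t)/P_baseline(f))` — a
divisive dB baseline. "A 2-s baseline taken 2 s before each trial" is
ambiguous; it is resolved as the 2-s window *ending* 2 s before the green
cue, which lies inside the preceding rest period. Maps cover 8-30 Hz and
-1 s to +4 s around imagery onset.

Group differences are tested per time-frequency cell by permuting subject
group labels (1000 draws by default, or exhaustive enumeration when the
number of distinct assignments is smaller — the exact test is also invariant
to group order), with BH-FDR at 0.05 across the full grid as one family.

## Problem sizes used by the test suite

The suite validates the chain at sizes chosen for the properties being
tested rather than for wall-clock fidelity: protocol counts run at the full
design (40 trials, 32 channels); chance-level and strong-effect decoding
checks run 20 and 3 seeds of 20-trial sessions (a reduced motor-strip
montage for the effect-monotonicity grid, 12-trial sessions, 20 seeds x 4
depths); statistical calibration runs 200 cohorts of 35 subjects at profile
level, with decoding accuracy replaced by a documented monotone surrogate of
ground-truth ERD depth (`0.5 + 0.45*depth` plus noise) — running full EEG
decoding for 7000 subjects is out of desk scale and adds nothing to the
property being tested (the correlation machinery, not the decoder). ERSP
group analyses run 8-20 subjects with 10-15 trial sessions.

## Known limitations

* The gfMDRM concretisation is one faithful reading of an underspecified
  method; it is not claimed to match the original authors' code.
* The simulator's oscillators are band-limited Gaussian envelopes on fixed
  carriers; real sensorimotor rhythms show richer non-stationarity.
* EDF output is 16-bit with a fixed ±500 µV physical range; signals beyond
  that range clip.
* Only two-class (imagery vs rest) decoding is supported, matching the
  protocol; no multi-class extensions.
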