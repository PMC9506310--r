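---
title: "Methods: connectivity eigenvalues, state segmentation, and eye features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity eigenvalues, state segmentation, and eye features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the model each
stage implements, the tunable parameters with their defaults and the
reasoning behind them, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement model

The object of study is the joint behaviour, under a 2×2
valence–arousal emotion design, of (a) EEG functional connectivity
summarized as three *distance-grouped eigenvalues* per analysis window
and (b) eye-movement features (fixations, saccades, left/right pupil).
"Eigenvalue" is used here as the field uses it for this quantity — a
scalar summary per channel-pair group — not as a linear-algebra term.

### Montage and pair groups

The montage is the standard 10–20 set of 19 electrodes minus Fz,
giving exactly 18 channels and `choose(18, 2) = 153` unordered pairs.
This particular subset was chosen because it contains every scalp region
the pair-group definitions need, includes F7 (named in discussions of
premotor involvement in eye-movement control), and reproduces the 153
pairwise features of an 18-channel cap. Electrode positions are an
idealized spherical layout: the outer ring (Fp1/2, F7/8, T3/4, T5/6,
O1/2) on the equator at the conventional 10–20 azimuths, Cz at the
vertex, Pz at 45° elevation, and F3/F4, C3/C4, P3/P4 constructed as
great-circle arc midpoints between the midline and ring electrodes (Fz
at azimuth 0°, elevation 45° serves as a construction point only). The
head is a sphere of radius 9.2 cm, a conventional adult value that makes
the "short distance < 10 cm" rule concrete: scalp distance is the
great-circle distance, and the short-distance group keeps only
adjacent-region pairs (frontal–temporal, frontal–central,
temporal–parietal, parietal–central) under that threshold.

Canonical pair order fixes the sign convention downstream: within a
pair, the channel of the higher-precedence region comes first, with
precedence occipital > prefrontal > frontal > temporal > central >
parietal. Positive LD_OF therefore means occipital power exceeds
frontal power. The precedence order itself is a convention; nothing
downstream depends on it beyond the documented sign.

### Preprocessing

* **Resampling** is Fourier-method rational-ratio resampling: the
  spectrum is truncated or zero-extended at the new Nyquist frequency.
  For band-limited content this has exactly unit passband gain, which
  matters because band power differences are the measurement. The
  signal is reflect-padded (about 1 s each side) so the method's
  periodicity assumption does not leak ringing into the retained span;
  the artifact mask is carried across by logical OR over contributing
  input samples.
* **Artifact handling** is amplitude-threshold masking: any sample
  exceeding 100 µV on any channel, dilated by ±0.2 s, is flagged.
  Flags never modify data; downstream windows with more than half their
  samples flagged are dropped. ICA-style ocular cleaning is out of
  scope; the synthetic data's artifacts are amplitude spikes, which this
  policy removes exactly.
* **Band filtering** uses the four classical bands — delta 0–4, theta
  4–8, alpha 8–12, beta 12–30 Hz — applied as the *squared magnitude
  response of a 4th-order digital Butterworth design* (bilinear
  transform with prewarped edges) on the FFT grid with reflect padding.
  This is the zero-phase forward–backward response of that filter
  computed in closed form. Two implementation facts drove this choice,
  both visible in the test suite's tolerances: the time-domain IIR
  recursion is ill-conditioned for narrow normalized bands (0.5–4 Hz at
  500 Hz) to the point of breaking linearity at the 10⁻⁶ level and
  overflowing for the delta band, while the closed-form magnitude is
  stable for any band and exactly linear. Zero phase is mandatory
  because pairwise phase differences are the downstream measurement.
  The delta band is realized as a low-pass, since a 0 Hz edge is not a
  realizable band-pass.
* **Spectra** (quality control only) are Hann-windowed one-sided FFT
  magnitudes of the longest unmasked run, restricted to 0–30 Hz.

### Wavelet phase and power

The complex Morlet mother wavelet is
`ψ(t) = (πB)^(-1/2) exp(−t²/B) exp(2πi f_c t)` with bandwidth parameter
`B = 1.5 s²` and unit centre frequency, so scale `a` analyses `1/a` Hz.
Per band, eight log-spaced frequencies span the band (delta floored at
1 Hz), plus the band's midpoint frequency (delta 2, theta 6, alpha 10,
beta 21 Hz) whose scale supplies the instantaneous phase. `B = 1.5` is
the conventional compromise between time and frequency resolution at
these bands; at beta it gives a ≈ 4 Hz spectral window, wide enough to
track power over 1 s windows yet narrow enough to isolate the band.
All of this sits in `waveletSpec()` so alternatives are one argument
away.

The transform is evaluated as an FFT-based linear convolution with the
conjugated, time-reversed, scaled wavelet — exactly the Riemann sum of
the transform integral with the signal taken as zero outside its
support. The kernel is truncated where its Gaussian envelope falls
below 10⁻¹² of peak, so the fast path and a brute-force evaluation of
the integral agree to ~10⁻¹² relative error (asserted at 10⁻⁶ in the
tests). Scales whose analysis frequency would exceed Nyquist are
rejected.

Windowing is 1.0 s with a 0.5 s hop: long enough to hold several beta
cycles and ~8 effective independent power samples, short enough to
resolve state changes at the few-second timescale the state analysis
targets.

### Pairwise connectivity and the strong/weak rule

Per window and pair: `PLV = |⟨exp(i(φ₁ − φ₂))⟩|` over the window's
unmasked samples, the circular-mean phase difference in (−π, π], and
the signed power difference `P₁ − P₂` (µV²). A pair is **strong** when
its absolute power difference is *below* the mean absolute power
difference of all pairs in that window and band — power differences
lower than the mean mark relatively strong (balanced) connectivity.
The referent of "mean power value" is read as the mean over the 153
pairwise absolute differences; that is the only reading that produces
a per-pair binary marking.

The group eigenvalue is the mean signed power difference over the
group's pairs, with the absolute-value variant (`abs_*`) emitted
alongside. Phase-based PLV is reported as its own column and is *not*
folded into the eigenvalue: the eigenvalue is explicitly a mean power
quantity, and the sign-as-directionality reading only makes sense for
a signed power difference. Reporting defaults to the beta band — the
band the headline connectivity contrasts concern — while all four
bands are computable.

### State segmentation

`incrementalKmeans()` z-scores the three eigenvalue columns (the groups
have different pair counts and magnitudes), then runs k-means for
k = 1…6 with 10 random restarts plus a warm start built from the
previous k's centroids and the worst-fit point. The warm start makes
inertia provably non-increasing in k — the "incremental" part — and
the whole procedure is deterministic given its seed.

The number of states uses an elbow rule: the first k whose relative
inertia improvement over k−1 falls below `relTol` marks the stall, and
the preceding k is chosen. The default `relTol = 0.5` was calibrated on
a 50-run battery spanning five scenario families: realistic generated
two-state sessions, realistic null sessions, and planted Gaussian 1-,
2- and 3-cluster series. Two findings shaped the value. First,
finite-sample k-means improvements from splitting a single isotropic
3-D Gaussian cluster run ≈ 15% per extra k (the theoretical optimum for
the best one-axis split is (2/π)/6 ≈ 10.6%), so thresholds near 10%
select k = 5–6 on *two*-cluster data. Second, eigenvalue series from
full EEG sessions are heavier-tailed than Gaussian — window power
estimates are skewed and the emotional state's spread scales with its
mean — so null sessions show spurious improvements of 0.30–0.45. At
0.5 the battery produced one error in 50 runs, and the only failure
mode is conservative: a weak-contrast session falls back to one state
(and is then flagged entirely non-emotional) rather than inventing
states. Clean two-cluster structure (separation ≥ 5 within-sd) sits at
improvements ≈ 0.97 and is unaffected.

With two states, the cluster whose centroid lies farther (Euclidean,
standardized space) from the mean of the first 10 windows is flagged
**emotional**: sessions begin pre-stimulus, so the early windows anchor
the non-emotional state. This baseline-distance rule is this package's
choice for an identification the underlying design leaves open
(self-report alignment would be an alternative when such data exist).
With any other k, every window is flagged non-emotional with a warning
— deliberately conservative.

### Eye movements

The detector is I-VT: 3-sample median pre-filter on gaze position,
angular velocity by *central difference* (two-sample span), saccade
threshold 30 deg/s, minimum fixation 100 ms. The central difference is
load-bearing at 60 Hz: with white fixation jitter of 0.2 deg RMS,
single-sample velocity noise is ≈ 17 deg/s per axis and crosses any
usable threshold, while the two-sample span halves it and empirically
eliminates false saccades at these settings. Saccade amplitude is
measured between the flanking fixation positions, each averaged over
up to 5 samples, so endpoint jitter does not bias it. Invalid samples
split events. Pupil change is percent change of the mean diameter from
a pre-stimulus baseline window (default the first 5 s) — a ratio
metric, invariant to per-individual diameter offsets. Features are
aggregated per condition × state by assigning each event to the state
segment containing its midpoint; empty cells are reported missing, not
zero. Fixation duration and saccade rate are the headline features;
counts and amplitudes are emitted alongside.

### Statistics

One-way ANOVA and Tukey HSD are delegated to `stats::aov()` /
`stats::TukeyHSD()` behind the module's own surface, with the
degenerate all-constant case defined as F = 0, p = 1 with a warning.
Tukey runs at the family alpha; the Bonferroni-style per-test alpha
(0.05/4 = 0.0125 for the design's four score tests) is computed and
reported *separately*, never stacked on top of the Tukey correction —
the analysis reports both artifacts without double-adjusting. Rows are
oriented so the difference is mean(condition 2) − mean(condition 1) in
the given condition order, and the reject flag is the interval
excluding zero. Eigenvalue-versus-eye-feature condition profiles are
compared by Spearman rank correlation over the four condition means;
with n = 4 this is descriptive only and no p-values are produced. The
ANOVAs treat conditions as independent groups, matching the pairwise
table structure being reproduced; repeated-measures modelling is a
known limitation, not an oversight.

## The synthetic generator

`generateEEG()` builds each channel as 1/f broadband noise (sd 3 µV)
plus four band-limited oscillations (delta 3, theta 2.5, alpha 4, beta
4 µV), a minimal spectral shape that still exercises the filters and
the wavelet transform meaningfully. Two mechanisms plant structure:

* **Phase coupling** (`couplingSpec()`): a shared band-limited source
  mixed as `√s·common + √(1−s)·private`, the second channel's common
  part delayed by the planted phase lag via the analytic signal. The
  shared-source form gives the planted PLV a closed-form expectation.
  A power ratio is realized symmetrically (√ratio up on the first side,
  1/√ratio down on the second) so total power stays level.
* **Regional gains** (`regionGains`): per-region amplitude factors on
  one band during scheduled states. This is the generative story behind
  the power-difference eigenvalues — regional activation differences —
  and it leaves phase structure untouched. The default study profile
  drives all three pair groups this way during emotional segments, with
  per-condition patterns echoing the qualitative findings the pipeline
  is meant to expose (frontal dominance when unpleasant-aroused,
  prefrontal dominance when pleasant, strong central–parietal activity
  when relaxed).

`generateGaze()` produces fixations with Gaussian jitter (sd 0.2 deg),
minimum-jerk saccades (duration 20 ms + 2 ms/deg) at scheduled times,
and pupil traces as baseline × scheduled excursion + AR(1) noise
(φ = 0.95, stationary sd 0.02 mm) for slow pupil dynamics. The default
session is 24 s — non-emotional first half, emotional second half with
a 10% pupil excursion, a saccade every 2 s — and `generateStudy()`
replicates it across participants × four conditions with random effects
on coupling strength (sd 0.05) and pupil responsiveness (sd 1 point),
drawing 9-point arousal/valence scores from the condition profile
(sd 1). Everything is deterministic given the seed; study sessions get
independent sub-seeds.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: volume conduction and
reference effects (planted couplings are genuinely bivariate; real
scalp EEG mixes sources), realistic artifact morphology (only amplitude
spikes), non-stationary band power outside the planted schedule,
blinks and tracker dropout, luminance-driven pupil responses, and
repeated-measures correlation between a participant's conditions
beyond the physiological random effects. Recovery results on this data
validate the *machinery* (filters, transform, estimators, clustering,
detectors, statistics), not claims about human physiology.

## Problem sizes and numerical choices

The test suite and acceptance script use 2000-sample signals for
transform-oracle checks, 20–30 s single sessions for phase and state
recovery, 94-window planted series over 20 seeds for state agreement,
30 null-study replicates (16 participants, 12 s sessions; 180 test
families) for type-I calibration, and a 4-participant, 24 s-session
study run twice for end-to-end determinism. These sizes were chosen so
each property is measured with comfortable precision while a full run
stays in the minutes range on one CPU.

Numerical conventions: phases live in (−π, π] with the wrap done in one
place; the wavelet kernel truncates at 10⁻¹² of its Gaussian peak;
k-means ties and restarts are fixed by the seed; zero-variance
eigenvalue columns are left unscaled rather than divided by zero;
16-bit EDF round-trips are accurate to the per-channel quantization
step; all CSV output is written with explicit formatting so reruns are
byte-identical, and run manifests carry md5 checksums of every output.

## Limitations

The directionality reading of the eigenvalue sign is a convention, not
a causal estimate — no Granger/transfer-entropy analysis is attempted.
The strong/weak marking depends on the within-window mean as a
reference and is therefore relative, not absolute. The elbow rule, even
recalibrated, can under-segment weak-contrast sessions (by design), and
the emotional-state identification needs the session to begin in a
non-emotional baseline. Scalp-map rendering is out of scope: spatial
results are delivered as tables keyed by channel pair.
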