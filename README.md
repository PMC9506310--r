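# emoconn

Emotion-state segmentation from EEG brain connectivity and eye movements.

`emoconn` is for researchers who study how emotional responses to visual
stimuli show up simultaneously in EEG functional connectivity and in eye
behaviour (pupil diameter, fixations, saccades) under the two-dimensional
valence–arousal model of emotion: a 2×2 design crossing valence
(pleasant/unpleasant) with arousal (aroused/relaxed). The package
implements the full analysis chain as tested, reusable functions, together
with a ground-truth synthetic-session generator so every stage can be
validated without access to human recordings.

## The method

Eighteen 10–20 scalp electrodes give `C(18, 2) = 153` channel pairs,
classified by scalp geometry into three groups:

* **LD_OF** — long-distance occipital ↔ (pre)frontal pairs,
* **LD_PF** — long-distance prefrontal ↔ temporal/central/parietal pairs,
* **SD** — short-distance pairs between adjacent regions
  (frontal–temporal, frontal–central, temporal–parietal,
  parietal–central) closer than 10 cm on a spherical head model.

EEG sampled at 500 Hz is artifact-masked, band-filtered (delta 0–4,
theta 4–8, alpha 8–12, beta 12–30 Hz; zero-phase Butterworth response),
and analysed with the complex Morlet continuous wavelet transform

    X(a, b) = |a|^(-1/2) ∫ x(t) ψ̄((t − b)/a) dt,
    ψ(t) = (πB)^(-1/2) exp(−t²/B) exp(2πi f_c t),

whose coefficients give each channel's instantaneous phase and band power.
Per 1 s window (0.5 s hop) and channel pair the pipeline computes the
phase-locking value `PLV = |⟨exp(iΔφ)⟩|`, the circular-mean phase
difference, and the signed band-power difference `P₁ − P₂`; a pair is
marked **strong** when its absolute power difference falls below the mean
absolute difference over all 153 pairs in that window. Each group's
**eigenvalue** (the field's term for this scalar, not a matrix eigenvalue)
is the mean signed power difference over the group's pairs; its sign
encodes directionality (positive LD_OF ⇒ occipital power exceeds frontal).

The chronological triplet series (e_LD_OF, e_LD_PF, e_SD) is z-scored and
segmented by incremental k-means (k = 1…6, warm-started so inertia is
non-increasing, elbow rule on the relative inertia drop) into states; with
two states, the cluster farther from the session's initial baseline is the
**emotional** state. Gaze streams (60 Hz) are segmented by a
velocity-threshold (I-VT) detector into fixations and saccades, pupil
change is percent change from a pre-stimulus baseline, and all eye
features are aggregated per condition × state. Group statistics use
one-way ANOVA with Tukey HSD intervals (plus the Bonferroni-style
per-test alpha 0.05/4 = 0.0125 reported alongside), and condition
profiles of eigenvalues versus eye features are compared by Spearman rank
concordance.

## Worked example

A synthetic 24 s session whose second half is "emotional": beta power is
regionally re-weighted and the pupils dilate 10% during that half.

```r
library(emoconn)
m   <- buildMontage()                 # 18-channel 10-20, spherical head
pg  <- classifyPairs(m)
table(pg$group)
#> LD_OF LD_PF OTHER    SD
#>    12    20   104    17

cfg  <- sessionConfig(duration = 24, seed = 7)
sess <- generateEEG(cfg, regionGains = c(prefrontal = 1.5, occipital = 1.4,
                                         central = 1.2, parietal = 1.2,
                                         frontal = 0.9))
series <- phaseAndPower(bandFilter(sess$rec, "beta"), "beta")
eig    <- groupEigenvalues(pairwiseConnectivity(series, pg))
lab    <- labelEmotional(incrementalKmeans(eig, seed = 17))
lab
#> StateLabels: 47 windows, chosen k = 2, 24 emotional
stateSegments(lab)
#>   start_s end_s emotional
#> 1     0.0  11.5     FALSE
#> 2    11.5  24.0      TRUE

gz <- generateGaze(cfg)
ev <- detectEvents(gz$rec)
aggregateByState(ev, gz$rec, lab, condition = "pleasant-aroused")
#>          condition         state mean_fix_duration fix_count saccade_rate
#> 1 pleasant-aroused non-emotional              1.94         6        0.435
#> 2 pleasant-aroused     emotional              1.93         6        0.481
#>   mean_saccade_amplitude pupil_change_left pupil_change_right state_time_s
#> 1                   6.93            -0.103              0.107         11.5
#> 2                   7.03             9.821              9.838         12.5
```

The 153 pairs split into the three distance groups plus the unclassified
remainder; the state machinery recovers the planted switch (true change
point 12 s, detected 11.5 s with 0.5 s windows) and the planted 10% pupil
dilation appears only in the emotional cell (≈ +9.8%, within noise of the
scheduled excursion).

A complete simulated study runs through `generateStudy()` →
`runPipeline()`, which writes eigenvalue, state, eye-feature, Tukey and
concordance tables plus a JSON manifest with md5 checksums; a thin CLI
over the same functions is installed at `inst/cli/emoconn.R`
(`simulate`, `run-all`).

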