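---
title: "Pulse-wise quality assessment for wrist PPG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-wise quality assessment for wrist PPG: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wrist photoplethysmography (PPG) is a quasi-periodic optical signal: each
heartbeat produces a pulse with an anacrotic (systolic) rise and a catacrotic
phase that, in clean recordings, shows a dicrotic notch and a diastolic wave.
Motion artifacts — ubiquitous in free-living recordings — corrupt this
morphology. The usability of a pulse is therefore graded three ways: **Bad**
(B, nothing distinguishable from noise), **Fair** (F, systolic peak
detectable, good enough for heart-rate work) and **Excellent** (E, systolic
and diastolic waves both visible, good enough for morphological analysis).
`ppgqc` implements the full pipeline from raw PPG + accelerometer streams to
trained quality classifiers.

## Preprocessing and pulse segmentation

PPG is band-passed with a second-order Butterworth filter, 0.5–12 Hz. Filters
are applied causally by default (`zero_phase = FALSE`), matching a pipeline
that could run online; zero-phase filtering is available behind the flag. The
detector is a two-moving-average event scheme: the filtered signal is clipped
at zero and squared; a peak-scale moving average (window 111 ms) is compared
against a beat-scale moving average (667 ms) plus an offset `beta * mean(x^2)`
with `beta = 0.02`. Contiguous super-threshold regions at least 111 ms long
are systolic blocks; the block maximum (of the filtered signal) is the
systolic peak, and the minimum between consecutive peaks is the systolic
foot. Pulse windows are half-open `[foot, next_foot)` with 0-based indices.

Two gates protect downstream stages: foot-to-foot intervals outside
0.3–1.5 s (40–200 bpm) are discarded as physiologically implausible, and
pulses with zero variance are dropped as degenerate. On noise-free synthetic
beat trains at 60 and 100 bpm the detector recovers 100 % of complete
interior beats with peak-time error at most 1 sample (the causal filter's
group delay at the pulse's dominant frequencies is below the 3-sample
tolerance we test against, so no zero-phase pass is needed).

Each pulse is z-score normalized with the *population* standard deviation
(divide by N); the same 1/N convention appears in the activity-index formula,
and using it consistently keeps the two stages coherent.

## Activity index and activity ranges

Accelerometer channels are linearly resampled to 64 Hz (to share the PPG
clock), band-passed at 0.025–10 Hz — which removes gravity before the vector
magnitude is formed — and reduced to `A_j = sqrt(x^2 + y^2 + z^2)`. The
activity index is computed exactly in the printed order (resample, filter,
magnitude): per 5-s epoch the population standard deviation `sigma`, and per
minute `Aind = sum of 12 sigmas`. Trailing partial epochs and minutes are
discarded, since both formulas assume full windows. A pulse belongs to the
minute containing its systolic foot — the foot is the pulse's anchor sample.

Activity ranges are the pooled quartiles of all `Aind` values across
recordings (quantile type 7, the common linear-interpolation rule), with
right-closed brackets: AR0 = [min, Q1], AR1 = (Q1, Q2], AR2 = (Q2, Q3],
AR3 = (Q3, max]. Sampling 100 pulses per range per recording yields
400 pulses per subject; with 31 subjects this is the 12,400-pulse labelled
set, and the subject-wise 70/30 split (round-half-up: 22 vs 9 subjects)
gives 8,800 training and 3,600 test pulses.

## Labels and agreement

Three raters vote B/F/E per pulse; unanimity wins, a 2-of-3 majority decides,
and total disagreement falls back to B (the conservative choice — an
ambiguous pulse is treated as unusable). Agreement is summarized by Fleiss'
kappa on the items-by-categories count matrix.

## The nineteen signal quality indices

Two indices come from the filtered accelerometer magnitude within the pulse
window (peak-to-peak and mean); seventeen from the pulse. Indices with a
`_noZ` suffix (median, mean, standard deviation of the un-normalized pulse),
plus amplitude, width and trough depth, use the filtered signal; everything
else uses the z-scored pulse, which is what makes them invariant to the
optically arbitrary PPG scale (verified to 1e-6 in the tests). Definitions
the literature leaves open are fixed as follows, each isolated in one
function so it can be swapped:

* **Entropy**: Shannon entropy of a 16-bin amplitude histogram of the
  z-scored pulse over [−4, 4], in nats.
* **SNR**: variance of the pulse over the variance of its residual from a
  125-ms moving-average smoothing, in dB — one parameter separating waveform
  from high-frequency noise.
* **SNR_Moody**: template-residual SNR. The template is an exponentially
  weighted running mean (weight 0.1) of z-scored pulses resampled to 64
  samples, seeded with the recording's first pulse;
  `10 log10(P_template / P_residual)`, capped at 60 dB for zero residual.
* **SigSim**: Pearson correlation with the previous pulse after linearly
  resampling it to the current length; the first pulse compares against the
  following one; zero-variance inputs return a floor of 0.
* **RelPower**: periodogram power in 1–2.25 Hz over total power, zero-padded
  to 256 samples so band edges are resolved for sub-second pulses.
* **Npeaks**: strict interior maxima; a plateau counts once at its first
  sample; no prominence threshold (mirroring a default peak finder).
* **ZR/ZDR**: sign changes divided by (length − 1); a sample exactly at zero
  inherits the previous sign so one crossing is never counted twice.
* **Skewness/Kurtosis**: standardized third/fourth central moments (kurtosis
  not excess).

ACC indices use the *filtered* magnitude, consistent with the activity
pipeline. Note the 0.025 Hz high-pass needs roughly a minute to settle the
1-g gravity step at recording start, so ACC indices in the first minute carry
a decaying transient; this is the expected behavior of the causal filter, not
a defect.

## Feature conditioning and NCA selection

Each feature column is shifted to strict positivity when needed
(`-min + 1e-6`), Box-Cox transformed at its per-feature maximum-likelihood
exponent (profile likelihood over [−5, 5]), and z-scored. Training and test
partitions are conditioned *separately* by default, exactly as the study
pipeline prescribes; `boxcox_from_train = TRUE` applies the training
parameters to the test set instead, the leakage-free variant. Because each
classification task fits its own conditioning, the cascade applies each
stage's training transform to the raw indices before that stage's model
(`cascade_predict(..., bq_transform =, hq2_transform =)`).

NCA maximizes the regularized expected leave-one-out accuracy of a
soft-neighbor rule. Distances are weighted Manhattan with weights entering
squared, `d_ij = sum_r w_r^2 |x_ir − x_jr|`, so effective weights are
non-negative without constraints. Optimization is batch gradient ascent from
`w_r = 1` with an adaptive step (halved whenever the objective would
decrease, slightly grown after accepted steps), stopping at a relative
objective change below 1e-6 or 200 iterations; the objective trace is
non-decreasing by construction. λ is tuned on a 20-point log grid spanning
[1e-4, 1] scaled by 1/n (the penalty must stay commensurate with the summed
objective), scored by ten-fold CV of a 1-nearest-neighbor rule in the fitted
metric; ties go to the smaller λ. Stability selection repeats the fit ten
times on 90 % subsamples — the source of run-to-run variation is not
specified by the method's description, and subsampling was chosen over random
restarts because the optimizer itself is deterministic — marking features
above 20 % of the run's maximum weight and keeping those marked in at least
80 % of runs. An empty stable set falls back to the full feature set with a
warning.

## Classifiers, hyperparameters, metrics

Three binary tasks: BQ (F∪E vs B), HQ1 (E vs B∪F) and HQ2 (E vs F). HQ2 is
trained and, by default, evaluated on ground-truth F/E pulses only; the full
cascade (BQ gate, then HQ2) is reported separately, since cascade error
propagation is a property of the composed system rather than of HQ2 itself.

Six families are tuned by minimizing ten-fold CV misclassification over at
most 30 configurations: tree (depth 1–30, min leaf 1–64), naive Bayes
(Gaussian or kernel-density class conditionals), SVM (linear / quadratic /
cubic / RBF kernel, cost 1e-3–1e3 log, kernel scale 1e-2–1e2 log), kNN
(k 1–64 log, Euclidean or Manhattan metric, uniform or distance-weighted
votes), ensemble (bagged random forest or gradient-boosted trees, 50–500
learners, learning rate 1e-2–1), and a one-hidden-layer neural network
(4–128 units, weight decay 1e-6–1e-1 log). The sequential search is
model-based: after a short random stage, a random-forest surrogate over the
evaluated configurations proposes the next candidate by expected improvement
(the spread across trees standing in for posterior uncertainty);
`search = "random"` gives plain random search for reproducibility studies.
Scores for the ROC are probabilities where the family provides them and the
signed margin for the SVM; AUC uses the rank (Mann-Whitney) statistic with
midrank ties. The remaining seven metrics come from the confusion matrix at
the model's natural threshold. No class rebalancing is applied — the natural
imbalance is part of the problem, and it is why the High-quality classifiers
show specificity above sensitivity.

Baselines: (i) the pulse-similarity comparator — SigSim thresholded at the
equal-sensitivity/specificity operating point, candidates being midpoints
between consecutive sorted unique training scores plus sentinels, ties to the
smaller threshold; (ii) a skewness-only SVM run through the identical tuning
harness.

## The synthetic cohort

The generator is the package's study bed, not a fixture: every stage of the
pipeline is exercised against its ground truth. Each beat is a systolic plus
diastolic Gaussian over a heart-period window (centers at 30 % and 62 % of
the period, widths 10 % and 14 %, diastolic amplitude ratio 0.35); periods
follow a per-subject heart rate (mean 72, sd 5 bpm) with 3 % lognormal
per-beat jitter. Each minute of a recording is assigned one of four motion
levels, near-equally and in shuffled order, so the pooled quartile ranges are
all populated for every subject; a level sets both the accelerometer burst
amplitude (0 / 0.05 / 0.25 / 0.9 g sinusoidal oscillation at 2–3.5 Hz in a
random direction, on top of a constant gravity vector and 4 mg sensor noise)
and the PPG noise level (band-limited noise with per-minute sd 0.03 / 0.15 /
0.5 / 0.8 of the systolic amplitude, 20 % lognormal jitter). Labels derive
from the generation parameters, not from re-detection: a beat is E when its
noise-to-signal ratio is below 0.08 and its diastolic wave was retained
(retention probability 0.62), F below 0.30, otherwise B. These values were
chosen once so that the pooled prevalences land near 48/37/15 % B/F/E — the
mix reported for real free-living wrist data — and motion minutes carry the
Bad pulses, reproducing the motion-quality coupling qualitatively. Simulated
raters corrupt the true label through a row-stochastic confusion matrix
(default 0.90 on the diagonal, errors mostly to adjacent classes).

What the generator does *not* emulate: arrhythmic or otherwise pathological
morphology, baseline wander from respiration or perfusion changes, sensor
saturation and optical skin-coupling effects, and non-stationary artifact
spectra. Passing tests therefore demonstrate that the pipeline's mechanics
and statistics behave as specified under controlled morphology and noise —
not that the trained classifiers transfer to any particular real device or
population.

## Problem sizes and numerical choices

The default study preset is 31 subjects at 30 minutes each (a desk-scale
stand-in for day-long wear; the cohort arithmetic — 12,400 labelled pulses,
8,800/3,600 split — is invariant to the per-subject duration as long as every
stratum holds 100 pulses, which the scheduled motion levels guarantee with a
wide margin). The acceptance script trains on a 1,800-pulse subsample of the
8,800 training pulses with 5-fold CV and 5 search iterations per family, and
runs NCA on 300 pulses with a 5-point λ grid — sizes chosen so the whole
script reruns in a few minutes while leaving the test-set evaluation at its
full 3,600 pulses. Package defaults remain the full sizes (ten folds, 30
iterations, 20-point grid).

Other numerical choices: Box-Cox exponents are searched in [−5, 5]; NCA
soft-neighbor rows with all-zero off-diagonal mass (isolated points) are
treated as contributing zero match probability; the SVM decision value is
oriented by the label order the fit saw; constant features (possible in
degenerate partitions) cannot be Box-Cox transformed and are dropped with a
warning naming them; metric denominators that vanish (MCC, kappa at
`P_e = 1`) yield NA rather than a silent zero.

## Known limitations

* The two-moving-average detector is tuned for resting-to-moderate heart
  rates; above 200 bpm the plausibility gate rejects genuine beats.
* Entropy and the template SNR are explicit stand-ins for under-specified
  definitions; both are isolated behind single functions.
* The kernel-density naive Bayes and the weighted kNN are intentionally
  simple reference implementations; they are quadratic in the training size
  and benefit from the training-size cap in large studies.
* Per-set Box-Cox conditioning (the default) lets test-set statistics
  influence the test features; the `boxcox_from_train` flag exists precisely
  because this is a known leakage vector, and the subject-wise split keeps
  the labels themselves leak-free either way.
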