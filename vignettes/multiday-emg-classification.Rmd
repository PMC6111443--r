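---
title: "Multiday EMG classification under day-to-day drift: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiday EMG classification under day-to-day drift: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Myoelectric pattern-recognition control classifies short windows of surface
EMG into discrete hand movements. Classifiers that look excellent in a
single laboratory session degrade over days: every re-donning of the
electrode array displaces it slightly around the forearm, skin-electrode
impedance changes, and muscle use varies, so the feature distribution drifts
between days far more than between two sessions recorded an hour apart on
the same day.

`emgdrift` implements a complete offline evaluation pipeline for this
problem: a synthetic multiday EMG generator, preprocessing, the Hudgins
time-domain feature set, three classifier families behind one train/predict
contract, the four cross-validation protocols that separate within-day from
between-day performance, and the classifier-comparison statistics. The
recording protocol it models is an 8-channel dry-electrode armband at
200 Hz, 7 movement classes (rest, close/open hand, wrist flexion/extension,
pronation/supination), 10 repetitions per movement per session, 2 sessions
per day, 15 days.

## The synthetic generator

No public multiday dataset exists for this protocol, so the generator is a
first-class module. Each session is built as:

1. **Carrier**: per channel, zero-mean Gaussian noise band-pass filtered to
   `carrier_band` (default 20-95 Hz) and normalized to unit RMS. Surface EMG
   energy concentrates above ~20 Hz, and 200 Hz sampling caps content below
   100 Hz.
2. **Activation**: each repetition of class *c* multiplies the carrier on
   channel *k* by `synergy[c, k'] * envelope(t)`, a trapezoidal envelope
   (0.5 s linear ramps) spanning the contraction. The default `synergy`
   matrix gives each active movement a smooth bump over adjacent channels of
   the electrode ring; the rest row is zero.
3. **Day drift**: `k'` indexes the day's *fractionally rotated* synergy row —
   a circular shift `delta_day ~ N(0, day_shift_sd)` in channel units with
   linear interpolation between electrodes. This models electrode-donning
   displacement around the forearm circumference, the dominant cause of
   between-day nonstationarity for a ring-shaped array. Each channel is also
   scaled by a per-day log-normal gain (`day_gain_sd`), modeling
   skin-impedance drift.
4. **Sessions**: the second session of a day adds the same two perturbations
   scaled by `session_jitter_scale` (default 0.25), encoding the assumption
   that same-day sessions are more alike than different days.
5. **Noise floor**: white noise of SD `noise_floor_sd` everywhere;
   relaxation periods and rest segments are noise-floor only. Each
   repetition carries an `exp(N(0, rep_amp_jitter_sd))` amplitude jitter,
   and movement order is randomized per session.

All randomness derives from one seed via per-component seed derivation, so a
config reproduces its dataset bit-for-bit.

### Chosen magnitudes

The drift magnitudes are not reported by any source, so they were fixed once
on physiological grounds. The study protocol we emulate used skin markers to
guide re-donning, limiting displacement to a fraction of the 45° electrode
spacing: `day_shift_sd = 0.3` channel spacings (~13°) with
`day_gain_sd = 0.15` puts the between-day error of the LDA baseline in the
low-teens-percent regime reported for marker-guided longitudinal armband
recordings, while within-day error stays near zero. A shift SD of half an
electrode spacing or more proved unrealistically destructive (between-day
errors near 70%). `noise_floor_sd = 0.05` sets the rest-class RMS about
26 dB below a unit-amplitude contraction.

### What the generator does *not* emulate

Amplitudes are arbitrary units (no millivolt calibration); there is no
motor-unit physiology, force-proportional recruitment, fatigue spectral
compression, or inter-subject anatomy variation. Most importantly, the raw
windows are amplitude-modulated Gaussian noise: class information lives
entirely in per-channel *second moments* (and their spatial pattern), never
in the mean waveform. Feature-based classifiers (MAV/WL/SSC/ZC capture
exactly these moments) and the CNN (whose ReLU nonlinearity rectifies before
pooling) handle this well; the raw-input stacked autoencoder (SSAE-r)
handles it poorly, because reconstruction-pretrained sigmoid encoders of
zero-mean inputs produce nearly symmetric encodings whose class-conditional
means coincide. SSAE-r is therefore close to chance on this synthetic data —
a stronger version of the real-data finding that SSAE-r is clearly the worst
of the four classifiers. Passing tests on this generator demonstrate
correctness of the pipeline and the *structure* of drift effects, not
real-data error magnitudes.

## Preprocessing

* **High-pass filter**: third-order Butterworth, 2 Hz cutoff, causal single
  pass — matching real-time prosthesis use, where zero-phase filtering is
  unavailable. The filter state is initialized to the steady-state response
  to the first sample (for a high-pass this equals filtering `x - x[1]`
  from zero state exactly), suppressing startup transients. A
  `zero_phase = TRUE` flag exposes forward-backward filtering.
* **Transition trimming**: 0.5 s removed from each end of every annotated
  segment, dropping movement onset/offset artifacts.
* **Windowing**: 150 ms windows, 25 ms steps — 30 x 8 samples at 200 Hz,
  `floor((N - L)/s) + 1` windows per segment, never crossing segment
  boundaries. Milliseconds round half-up to samples; at 200 Hz the defaults
  are exact (30 and 5).

Rest windows come from rest-labeled segments exactly like any other class;
un-annotated relaxation gaps are never windowed.

## Features and classifiers

The four Hudgins time-domain features per window per channel (4 x 8 = 32):
MAV `mean(|x|)`, WL `sum(|diff(x)|)`, SSC and ZC counts with a zero
threshold. With threshold zero the amplitude conditions are vacuous and the
strict product tests (`< 0` for ZC, `> 0` for SSC) mean exact zeros never
count — the deterministic reading of the common convention. Feature order is
fixed (MAV, WL, SSC, ZC), flattened channel-major.

* **LDA**: pooled within-class covariance, class-frequency priors,
  discriminant `g_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`.
  A ridge of `1e-6 * mean(diag(S))` keeps `S` positive definite. LDA
  consumes unscaled features (its predictions are invariant to invertible
  affine feature maps).
* **SSAE**: two sparse autoencoder layers (sigmoid encoder, linear decoder)
  pretrained greedily by Moller's scaled conjugate gradient on the
  reconstruction loss plus L2 weight decay (1e-4) and a KL sparsity penalty
  (weight 0.01, target activation 0.5), then a softmax head trained
  supervised with cross-entropy, also by SCG. Hidden sizes are (32, 16) for
  the 32-dimensional feature input and (100, 50) for the 240-dimensional
  raw input. Cross-entropy was chosen for the head (the alternative, MSE on
  one-hot targets, is strictly worse-behaved with softmax outputs).
  End-to-end fine-tuning exists behind a flag but is off by default: the
  method under study is greedy pretraining + supervised head. SCG stops at
  `max_iters` (default 400 per layer) or gradient norm < 1e-6.
  Input scaling: per-feature min-max to [0, 1] for features (the sigmoid
  operating range); per-channel z-scoring for raw windows.
* **CNN**: valid (unpadded) 3 x 3 convolution with 32 filters
  (30 x 8 -> 28 x 6 x 32), ReLU, 3 x 1 max pooling with stride equal to the
  pool size and floor division (-> 9 x 6 x 32), one fully connected layer to
  7 logits, softmax. The padding and pool-stride conventions are pinned by
  parameter-count tests (320 convolution, 12,103 FC parameters). Training is
  SGD with classical momentum (`v <- m v - lr g; w <- w + v`), lr 0.1,
  momentum 0.95, L2 1e-3, batch 256, 25 epochs, shuffled batches, no early
  stopping. Weights initialize as zero-mean Gaussians scaled by fan-in
  (conv/FC) and symmetric uniform (autoencoders), all seeded.

Ties in every argmax break toward the lower class index. All three families
sit behind one `classifier_spec` fit/predict contract and are
interchangeable in every protocol; each fold retrains from scratch with a
fold-derived seed (no adaptation across folds).

Implementation note: the convolution is an im2col matrix product and the
autoencoders are dense matrix arithmetic, so the whole package is pure R
over BLAS; at the problem sizes used here compiled code would not change
what is feasible.

## Evaluation protocols

The classification error (CE) is the fraction of wrongly classified
windows; accuracy is 1 - CE. Partitioning is always at provenance level, so
overlapping windows cannot leak across the train/test boundary:

| protocol | folds | partition unit |
|---|---|---|
| within-session | one per repetition (10) | repetition |
| between-sessions | 2 | same-day session |
| pairs-of-days | n(n-1)/2 pairs x 2 directions | day |
| leave-one-day-out | one per day (15) | day |

Within-session folds hold out one repetition of *every* movement — the only
leakage-safe reading given 150 ms windows with 25 ms steps. For a day pair,
the two directional errors are averaged into the single pair value
(rendered as the upper/lower triangles of a day x day table for two
classifiers at once). Fold builders are exported separately
(`within_session_folds()` etc.) so the leakage audit can inspect the exact
index sets the protocols use.

## Statistics

`anova_two_way()` fits the balanced fixed-effects two-way ANOVA (classifier
x time level) through `stats::aov()`, with the interaction when cells have
replicates and without it for single replicates; subjects enter as
replicates (consistent with reporting means across subjects). CE values
enter untransformed. An all-equal table is flagged degenerate and reported
as not significant rather than producing 0/0 F statistics.
`posthoc_pairwise()` runs Tukey-Kramer HSD comparisons on the classifier
factor via `stats::TukeyHSD()`, using the residual mean square; significance
is judged at alpha = 0.05 and always agrees with the simultaneous CI
excluding zero. Calibration is verified in the test suite: the
classifier-factor F test rejects at 5.0% +- 1 point under the null over
thousands of simulated balanced tables.

## Problem sizes used in tests and the acceptance script

The full protocol (15 days x 2 sessions x 10 repetitions x 8 s trials)
produces ~240,000 windows per subject; the package's correctness does not
depend on that scale, so the shipped test suite and `scripts/acceptance.R`
run reduced configurations — typically 2-3 days, 3 repetitions, 1.5-2.5 s
contractions, SCG budgets of 150 iterations — and say so in their reported
`n` fields. Two sizing choices matter scientifically: within-session folds
need a few hundred training windows for the autoencoders to fit at all, and
the mean pairwise-day error needs at least 3 days (3 pairs) before it stops
being dominated by a single day-shift draw. Drift and noise parameters are
never reduced; they are the package defaults everywhere.

## Known limitations

* SSAE-r is near chance on this generator (see above); its qualitative
  ordering (worst of the four) matches the real-data finding, but its
  absolute errors here overstate the real-data gap.
* The generator's drift is stationary across days (no slow trends or
  within-session fatigue drift).
* Single-subject synergies: subjects differ only by seed, not by
  systematically different channel layouts.
* The evaluation is offline and window-level; no majority-vote
  post-processing, confusion matrices, or real-time latency accounting.
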