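---
title: "Synergy-based decoding of grasp kinematics from EEG: models, parameters and numerical behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synergy-based decoding of grasp kinematics from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
movement model, the decoding pipeline, what the synthetic cohort generator
does and does not emulate, and the numerical decisions taken where the design
was genuinely open.

## 1. The movement model

A grasp's joint angular velocities are modeled as a weighted sum of a few
fixed spatiotemporal patterns (kinematic synergies). Stacking one flattened
velocity epoch per trial (joint-major: joint 1's full epoch, then joint 2's,
…) gives the trials × (joints · samples) matrix `V`, which is factorized by
singular value decomposition, `V = U Σ S`. The rows of `S` are orthonormal
synergy candidates; component *i* carries the variance fraction
`σᵢ² / Σ σ²`. `select_synergies()` keeps the smallest leading set whose
cumulative fraction reaches the threshold (default 0.85, inclusive: a
cumulative fraction exactly equal to the threshold qualifies — the standard
reading of an "at least this much variance" rule).

Three decisions here were open and are fixed as follows:

* **No mean-centering before the SVD** (`center = FALSE` by default). The
  factorization is applied to the velocities themselves rather than to their
  covariance; a `center` argument exists for sensitivity analysis.
* **Sign convention.** An SVD is unique only up to per-component sign flips.
  Each synergy row is flipped so its largest-magnitude element is positive
  (the matching column of `U` is flipped with it), making repeated
  decompositions bitwise identical and synergy plots comparable across runs.
* **Weights by orthonormal projection.** Because the rows of `S` are
  orthonormal, the least-squares weights are simply `C = V Sᵀ`; the
  normal-equations solution coincides with it, which the test suite checks
  explicitly.

`reconstruction_error_curve()` reports both the tail-singular-energy form of
the reconstruction error and the directly computed normalized Frobenius
residual; their agreement to 1e−10 (the optimality of truncated SVD) is used
as a numerical self-check.

## 2. EEG features

Preprocessing subtracts the mean of a resting-baseline segment, removes the
linear trend, and band-pass filters to 0.1–56 Hz with zero phase. The
band-pass is realized as a cascade of a 2nd-order Butterworth high-pass at
0.1 Hz and a 4th-order Butterworth low-pass at 56 Hz, each run
forward–backward: a single 8-pole transfer-function band-pass with a corner
at 0.1 Hz of a 256 Hz rate is numerically fragile in the coefficient form the
filtering backend uses, while the cascade is well conditioned and has the
same zero-phase passband.

Features are extracted from the 2 s post-stimulus epoch with 500 ms sliding
windows overlapping by 375 ms (step 125 ms), which yields exactly
13 windows — hence 13 features per electrode and 32 × 13 = 416 features per
trial. Each feature is the band-integrated power spectral density of the
window: a Hann-tapered periodogram integrated over the band by the trapezoid
rule, divided by the band width by default (so features are band-average PSD
in µV²/Hz; `normalize = FALSE` gives the raw integral in µV²). Two estimator
notes:

* Welch averaging inside a 500 ms window would leave too few sub-segments to
  be useful; a single Hann-tapered periodogram per window is used instead.
* The trapezoid rule gives band-edge bins half weight. For a band whose edges
  carry spectral mass (e.g. an exactly-on-bin 10 Hz tone integrated over
  8–12 Hz) the integral under-counts by the half-weighted edge bins; for
  bands whose edges sit on low-power bins the integral matches the Parseval
  value to high accuracy. The tests document both regimes.

Band edges follow the sensorimotor convention: delta 0.1–4, theta 4–8, mu
8–12, beta 18–30, gamma 30–56 Hz (delta's lower and gamma's upper edge capped
by the analysis filter). The 12–18 Hz interval belongs to no named band and
is covered only by the full-band feature set. Features are linear power by
default; `log_power = TRUE` switches to log₁₀ power.

Across electrodes, dimensionality is reduced by PCA fitted on training trials
only (`fit_feature_reducer()`), retaining the smallest number of top-ranked
components reaching 90% of feature variance by default (an integer rule gives
a fixed count). The fitted means and loadings are stored, held-out subjects
are projected with them, and the retained count is logged per fold — it is
one of the main run-to-run variation sources.

## 3. The decoder and its evaluation

The neural decoder is the multivariate linear regression `C = X β`, solved by
minimum-norm least squares from the SVD of `X` (rank-deficient fits fall back
to the minimum-norm solution with a warning; condition numbers are logged).
One regression is fitted per grasp type by default — the independency
statistic of Section 5 sums over per-task coefficient matrices, and per-task
fits match that structure — with a pooled option.

**Intercept handling.** The regression model itself carries no explicit
intercept term. An early implementation fitted slopes only, on the grounds
that the PCA centering of the features absorbs offsets. That is insufficient:
the *weights* of each task have a nonzero mean that centered features cannot
represent, and on noise-free synthetic data the decoder plateaued visibly
below perfect recovery. The package therefore centers both sides within each
fit and restores the training-set means at prediction time — operationally an
intercept estimated from training data only, never exposed as a coefficient.
With this correction, noise-free cohorts decode to ρ = 1 within numerical
precision, which the test suite asserts.

**Cross-validation.** Generalization across people is evaluated by repeatedly
splitting the subjects in half at random (5 train / 5 test for ten subjects;
floor/ceil for odd counts): synergy extraction, feature reduction and the
regression see training subjects only, and the held-out subjects are decoded
from their EEG alone. Ten such shuffled splits are the default. Note these
are independent re-shuffles, not a partition into ten disjoint folds — with
ten subjects and half/half splits a disjoint 10-fold partition cannot exist.
Decoded weights are recombined with the training synergies and scored per
trial and per joint by the Pearson correlation over the epoch's samples;
accuracy is reported as 100·mean(ρ) percent and error as 1 − |ρ|, so
anti-correlated reconstructions count as zero error by definition. The
averaging order — ρ per (trial, joint), then means at whatever grouping is
requested — is fixed and recorded here because the alternative orders
(per-joint concatenation across trials, per-trial averages first) give
slightly different aggregates. A constant recorded or decoded trace leaves ρ
undefined; such trials are flagged and excluded from aggregates rather than
silently scored as zero.

## 4. The synthetic cohort generator

No human recordings ship with the package, so the generator is a first-class
module whose defaults define the study conditions everything else is tested
under.

**Protocol.** Ten joints at 125 Hz, 32 EEG channels at 256 Hz, 6 grasp types
× 30 repetitions (180 cue events per subject), 2 s post-stimulus epochs, a
4 s resting stretch for baselines and 1 s inter-trial gaps during which the
hand ramps back to the flat calibration posture (every trial's angles start
at 0°).

**Kinematics.** A hidden set of orthonormal synergies (smooth random
multi-joint curves) is shared by all subjects — the cross-subject
generalization the decoder exploits is precisely this shared structure; an
optional `synergy_jitter` parameter perturbs each subject's synergies and
defaults to 0 because no within- versus across-subject variability magnitude
was available to calibrate it. Per trial, weights are drawn from a
grasp-type-specific Gaussian; velocities are `cᵀS` plus white noise,
integrated to angles. Two calibrated structures matter:

* *Variance profile.* Synergy energies follow the fixed profile
  (0.263, 0.195, 0.163, 0.137, 0.126, 0.116) of the signal variance, and the
  default kinematic noise (6 deg/s against ≈20 deg/s rms velocities, ≈8% of
  total variance) places the cumulative variance of `V` at ≈0.81 after five
  components and ≈0.92 after six — so the 85% rule selects six synergies with
  a wide margin on both sides at training-fold sample sizes.
* *Orthogonalized grasp means.* The grasp-type mean weight vectors are drawn
  randomly and then orthogonalized and rescaled so the weights'
  second-moment matrix is exactly diagonal with the profile above; without
  this, correlated grasp means concentrate variance in fewer SVD components
  and the realized spectrum would not follow the designed profile. Half of
  each synergy's variance is between grasp types and half is trial-to-trial
  (`within_frac = 0.5`), so decoding genuinely has to track individual
  trials, not just grasp prototypes.

**EEG.** Inside each epoch the signal is a 10 Hz (mu-band) carrier whose
instantaneous power is affine in the trial's weights:
`q(t) = α_e + env(t) · (G c)_e`, where `env` is a fixed post-stimulus shape
(brief desynchronization dip, then a synchronization rebound), `G` is a
sparse non-negative coupling concentrating each synergy on a Gaussian
neighborhood (falloff 0.12, hard zero beyond radius 0.45) around spread-out
sensorimotor electrodes (greedy max–min-distance centers seeded at C3), and
`α_e` is a resting-power baseline sized so `q` stays positive. Because the
windowed band-power of `sqrt(q(t))·sin(2πf₀t)` is — by Parseval's identity —
a fixed linear functional of `q` whenever the band captures the carrier's
energy, the extracted features equal `baseline + coupling·c` *exactly* (to
spectral-leakage error below 1e−6 relative), and `feature_coupling()` exposes
that affine map for parameter-recovery tests. Feature noise is injected
through the minimum-norm pre-image of the same linear functional, so even
noisy features hit their target values. The carrier sits on an FFT bin of the
128-sample analysis window, keeping Hann leakage inside the band.

Outside the epochs, the background is AR(1) broadband noise (high-passed at
generation so it is invariant under the pipeline's own 0.1 Hz high-pass) plus
a resting rhythm that continues the epochs' carrier at matching amplitude and
phase; the broadband part cross-fades to zero around each epoch. These
continuity choices are deliberate: amplitude, phase or offset steps at epoch
boundaries ring through the zero-phase filters into the epochs and acted as
un-modeled feature noise.

The default feature-noise level (`noise_sd_feat = 0.05` µV²/Hz, roughly half
the within-task feature signal on coupled electrodes) puts the default
cohort's decoding accuracy around 90% — the synthetic data is intentionally
cleaner than real scalp EEG, whose artifacts, non-stationarity,
volume-conduction mixing and inter-subject physiological variability the
generator does not attempt to model. Passing the pipeline's tests therefore
demonstrates the *correctness of the computation* (leakage-free fitting,
exact linear-algebra identities, recovery of planted structure), not that any
particular accuracy will be achieved on real recordings. Real data enter
through the delimited/EDF readers, and excluded-trial flags stand in for the
manual artifact rejection a human study would perform.

## 5. Independency maps

To localize each synergy's cortical involvement, the regression is refitted
per electrode neighborhood (the electrode plus all montage electrodes within
radius 0.25, the immediate grid neighbors) and the squared coefficients are
summed over coefficients and tasks: `D_n(e) = Σₖ Σₘ β²ₘₖ`. Two implementation
choices make this statistic meaningful:

* The neighborhood features pass through the same PCA reduction the
  whole-scalp decoder uses, with the component count additionally capped at a
  tenth of the per-task trial count so the per-task regressions never
  interpolate, and the retained component scores are standardized before the
  fit. Without the standardization, a *low-variance, uninformative*
  neighborhood needs enormous coefficients to fit anything and dominates the
  map for exactly the wrong reason — squared-coefficient maps are only
  comparable across electrode sets on a common feature scale.
* A correlation statistic (mean squared Pearson correlation between
  neighborhood features and each synergy's weights, summed over tasks) is
  computed alongside the density, since either statistic can reasonably back
  a topographic map; both are returned so users can compare them.

`band_modulation()` repeats the computation with features restricted to each
named band. On synthetic cohorts the encoding band's map dominates and the
planted neighborhoods attain the largest densities, which is the package's
parameter-recovery test for this statistic.

## 6. Numerical choices and degenerate inputs

* Rank decisions use a relative singular-value cutoff of 1e−10; minimum-norm
  solutions are used for rank-deficient systems, with a warning and condition
  number logged.
* The variance-threshold comparison is inclusive with a 1e−12 guard against
  floating-point under-run of an exactly-met threshold.
* `angular_velocity` is a first-order forward difference (the simplest
  faithful reading of differentiating recorded angles); smoothing is left to
  optional pre-filtering of the angle streams, off by default. Velocity
  epochs index from the cue-onset sample, half-open `[onset, onset + epoch)`.
* Kinematic and neural epochs are kept at their native rates (250 and 512
  samples) and linked only at the trial level — the decoder operates on
  per-trial weights, so no cross-rate resampling is ever needed.
* Degenerate inputs error early and specifically: empty matrices, epochs past
  the recording end (naming the trial), mismatched layouts, unfitted
  reducers, test features produced with the wrong reducer, correlations of
  constant series.

## 7. Problem sizes

The shipped tests exercise the full protocol where the check depends on it
(180-trial subjects, two-subject default cohorts for selection and map
recovery) and reduced cohorts (3 synergies × 4 joints, 2–4 subjects, 4–6
repetitions) for algebraic properties, keeping the suite under a couple of
minutes. The study-level evaluation in `scripts/acceptance.R` runs the full
default configuration: 10 subjects, 180 trials each, 10 shuffled 5/5 folds,
reporting the overall mean Pearson accuracy over the resulting 90 000
(trial × joint) scores.

## 8. Known limitations

* The generator's EEG is a band-power encoding device, not a biophysical
  simulation: no volume conduction, no eye/muscle artifacts, no 1/f activity
  inside epochs, no channel offsets, and a single shared carrier frequency.
* Per-subject synergy variability defaults to zero; enabling
  `synergy_jitter` degrades cross-subject transfer, but no empirical
  calibration of its magnitude is built in.
* The EDF support covers continuous, equal-rate, 16-bit recordings (the
  common case for the montages used here); annotations/EDF+ events are out of
  scope — trial events travel in the separate events table.
* Accuracy aggregates assume the per-(trial, joint) ρ averaging order
  described in Section 3; other orders are easy to compute from `tidy(cv)`
  but are not built in.
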