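---
title: "batroll: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{batroll: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`batroll` simulates a developing echolocator — modelled on the big brown
bat, *Eptesicus fuscus* — that learns to orient its head towards a sonar
target without any supervision.  The agent sits at the centre of a
perceptual-motor loop:

1. it emits a downward FM call (70 to 15 kHz, 500 kHz sampling, duration
   drawn from a gamma distribution with shape 8.0 and scale 0.3 ms);
2. the echo from a point target at a fixed nominal distance is rendered
   binaurally through direction-dependent head-related transfer
   functions (HRTFs) and jointly normalized, so only relative binaural
   and spectral structure survives;
3. the two waveforms are cut into fine (50-sample) and coarse
   (100-sample, decimated by 2) windows with stride 5 and encoded by six
   GASSOMs — generative adaptive subspace self-organizing maps — one per
   (scale, channel) combination, where channel is binaural, left or
   right.  Each GASSOM unit is a two-dimensional subspace; its response
   is the squared projection of the (unit-norm) window onto the
   subspace, and the reconstruction error is the squared residual;
4. per-GASSOM responses are average-pooled over windows and concatenated
   into the state feature vector (2400 dimensions at full scale);
5. a one-hidden-layer tanh policy maps the feature vector to yaw and
   pitch commands; during learning, commands are drawn from a Gaussian
   around the policy mean (exploration sd 10 deg) and clipped;
6. the reward is the negative reconstruction error averaged over
   scales, channels and windows — the active-efficient-coding signal —
   and a natural actor-critic updates the policy and a linear critic;
7. the head pose follows a Fick gimbal (yaw, then pitch, then torsion)
   whose torsion is the Listing value (half the yaw-pitch product,
   evaluated in radians) perturbed by a random head roll drawn from an
   echo-to-echo AR(5) process; one roll sample is consumed per echo.

Each target is held for a 20-iteration episode, after which a new
direction is drawn uniformly from the horizontal-angle x elevation
training rectangle.  The package runs the loop at four roll conditions
(marginal roll sd 0, 10, 20 and 30 deg), mirroring the observation that
roll variability of about 10 deg accompanies sonar tracking in perched
bats, and asks how localization accuracy and speed change with the roll
magnitude.

## Why rolls should matter

A head roll rotates the interaural axis about the head direction.  In
head-centred coordinates it rotates the *cue pattern* about the (0, 0)
direction: a target that sits straight ahead is the unique fixed point,
while a target at any eccentric direction sees its interaural cues
jitter from echo to echo.  Two consequences follow.  First, elevation
offsets — which carry only weak monaural (spectral-notch) cues in a
roll-free world — are converted into strong binaural cues whenever the
head is tilted.  Second, once the learned dictionary concentrates on the
statistics of near-frontal echoes, the reconstruction-error surface
acquires a minimum at (0, 0) that rolls deepen and symmetrize, because
(0, 0) is the only direction whose windows look the same under every
roll.  The reward-maximizing policy therefore drives the target towards
(0, 0), faster and more accurately the larger the roll variability.
`error_surface()` and `rotate_surface()` expose this mechanism directly:
surfaces probed under fixed +20 and -20 deg rolls are rotations of one
another about the origin, exactly as the geometry predicts.

## Sign conventions

All modules share one table (see `?batroll`): right-handed frames with
+X forward, +Y left, +Z up; Fick angles are the native angles of
`R_Z(yaw) R_Y(pitch) R_X(torsion)` (positive yaw leftward, positive
pitch downward); direction angles are azimuth positive *rightward* and
elevation positive up, so a positive yaw command moves the head to
positive azimuth; positive ITD/ILD mean the right ear leads / is
louder.  The horizontal angle `alpha = asin(sin(theta) cos(phi))` is the
cone-of-confusion coordinate in which HRTFs are gridded.  The Listing
torsion is computed with the yaw-pitch product in radians: the paper-free
alternative (degrees) would produce torsions of hundreds of degrees for
ordinary poses, which is physically absurd; the radian form is the
standard small-angle approximation of Listing's law.

## The head-roll model

`default_roll_model()` ships an AR(5) surrogate for bat head-roll
dynamics.  The measured motion-capture series is not redistributed;
instead the default model is built from five explicit poles — a slowly
decaying postural oscillation (modulus 0.9, period about 12 echoes), a
faster waggle rhythm (modulus 0.85, period about 4.5 echoes) and a
rapidly alternating component (real pole -0.75) — and calibrated so the
marginal standard deviation equals the requested sigma exactly (via the
Yule-Walker variance identity).  The package also provides the full
estimation pipeline used to build such a model from data: the biased
sample ACF (`sample_acf()`), least-squares fitting of the AR-implied ACF
to a sample ACF over lags 1-40 (`fit_ar_to_acf()`, with a stationarity
penalty and Yule-Walker initialization), and blocked cross-validation
for the order (`select_order_cv()`: five contiguous validation blocks;
a paired one-standard-error rule treats a smaller order as tied with
the best unless the best wins by more than one standard error of the
fold-wise score difference, so effective ties resolve downward).  The sigma = 0 condition is represented by a
degenerate constant-zero roll stream rather than a fitted model.

## Synthetic HRTFs

Measured bat HRTFs are not shipped; `synthetic_hrtf()` builds a
spherical-head stand-in on a horizontal x elevation grid of the frontal
hemisphere (+/-80 deg):

* ITD from the Woodworth formula `a (alpha + sin alpha) / c` with a bat-
  scale head radius of 7 mm (ITD span about +/-50 us, matching the range
  probed in the tuning-curve protocol), applied as exact fractional
  delays;
* ILD from a first-order head-shadow shelf (corner frequency `c / 2 pi
  a`), applied as a zero-phase magnitude response so the rendered ITD
  equals the Woodworth value exactly;
* an elevation-dependent Gaussian spectral notch (centre sweeping 35 to
  65 kHz as elevation goes from -40 to +40 deg, depth 15 dB), on by
  default, so elevation is learnable even without rolls — as with real
  HRTFs, where pinna filtering provides monaural elevation cues.

Interpolation between grid nodes is bilinear in per-ear magnitude and
(analytically continuous) phase, exact at the nodes.  Rendering
convolves the call with the two impulse responses and normalizes the
stereo pair jointly to unit RMS, preserving the left/right ratio
exactly.  No propagation delay, distance attenuation, emission-beam
directionality or multi-path is modelled.

## GASSOM details

The generative model behind the coder treats each window as drawn from
one of J two-dimensional subspaces with additive isotropic noise, with
the active subspace following a sticky first-order Markov chain across
consecutive windows (stay probability 0.9, otherwise uniform) — a
concrete reading of the temporal-smoothness constraint that makes units
phase-invariant, like auditory/visual complex cells.  Encoding computes
the filtering posterior of that chain.  Learning takes, for each unit, a
neighborhood-weighted batch step towards the response gradient
`x (x' Phi)` followed by Gram-Schmidt re-orthonormalization; units sit
on a square grid (20x20 at full scale) with a Gaussian neighborhood
annealed from radius 3 to 0.5, learning rate annealed from 5e-2 to
2e-3, and assignment noise sd annealed from 0.5 to 0.15.  Windows are
unit-normalized before encoding (scale-free errors; the binaural
concatenation is normalized after concatenation, so interaural level
structure survives), and zero-norm windows are dropped.

## The actor-critic

The critic is linear in the features; the actor is the spec'd
one-hidden-layer tanh network.  Both see online-standardized features
(running mean and variance), which makes learning rates meaningful
regardless of representation scale.  Learning is an incremental
compatible-feature natural actor-critic: the TD error (discount 0.3; no
bootstrapping across targets) updates the critic by a normalized step
and a normalized-LMS regression `w <- w + lr (delta - psi' w) psi /
||psi||^2` estimates the advantage in the compatible basis `psi = grad
log pi`; the actor then steps along `w`, which is the natural gradient.
`w` carries a forgetting factor (0.99 per step) so advantage directions
decay once the policy has absorbed them.  The discount, learning rates,
clip bound (+/-30 deg per iteration) and forgetting factor are
engineering choices documented here; they are not taken from the
reference study, which reports none.

## Scaled-down profile and problem sizes

The full profile (400-unit GASSOMs, 500 hidden units, thousands of
training targets) reproduces the reference architecture but takes hours
on one CPU.  The `"ci"` profile used by the test-suite experiments runs
64-unit GASSOMs (8x8 grids), 128 hidden units, an HRTF grid with 20-deg
spacing, targets drawn from the +/-40 deg rectangle, and training
budgets of a few hundred targets; analysis grids are correspondingly
coarsened (error surfaces on 10-deg grids with a handful of call
durations and rolls instead of 81 x 81 x 30 x 100).  These sizes were
chosen as the smallest at which the qualitative phenomena - reward
growth, frontally-shaped error surfaces, and the benefit of rolls - are
visible in minutes.  What passing scaled-down tests shows is that the
mechanism behaves as described at reduced scale; it does not certify
the quantitative statistics of the full model (F statistics on
thousands of trajectories, percentages of response classes), which
require full-profile runs and, for some comparisons, measured bat
HRTFs that are not redistributable.

## Analysis battery

* `fit_step_response()` fits `s(t) = A exp(-t / tau) + B` by profiling
  the linear (A, B) subproblem over a log-spaced tau grid with local
  refinement; `tau` is the localization time constant.
* `steady_state_mse()` implements the final-iteration mean squared
  error, optionally normalized by the zero-roll reference.
* `characterize_basis()` fits a Gaussian-windowed linear chirp jointly
  to the two components of a binaural basis vector (shared frequency
  track and envelope; per-component amplitude and phase).  ILD is the
  amplitude ratio in dB; ITD is the phase difference over `2 pi fc`.
  Because a phase-delay ITD is only defined modulo the carrier period,
  round-trip accuracy is assessed on the wrapped difference; ITDs
  beyond half a period of the unit's centre frequency alias, exactly as
  phase-sensitive neurons alias.
* `probe_pure_tones()` runs the standard physiology protocol: best
  frequency from 10-70 kHz in 1-kHz steps (equal amplitude, zero phase
  difference), then an ILD sweep (-40..40 dB, 1 dB) and an ITD sweep
  (-80..80 us, 1 us) at BF, max-normalized, averaged over onset phases.
* `classify_tuning_curve()` labels curves monotonic (|Spearman rho| >=
  0.9), peaked (single interior maximum, prominence >= 0.3), cyclic
  (dominant nonzero Fourier component explaining >= 50% of variance,
  at least one full period in range) or flat.  Monotonicity is tested
  first, then peakedness, then cyclicity, so a single bump is peaked
  rather than cyclic; the thresholds are explicit stand-ins for label
  criteria the reference study does not state.
* `compare_distributions()` returns the KL divergence (with 1e-6
  additive smoothing where needed) and the Bhattacharyya coefficient;
  `cue_histogram()` bins ILDs in 2-dB and ITDs in 5-us bins.
* `effect_stats()` computes the one-way ANOVA F (explicit sums of
  squares, cross-checked against `stats::aov` in the tests) and pairwise
  Cohen's d with pooled standard deviations.

## Degenerate inputs and numerical choices

Gimbal lock (|pitch| = 90 within 1e-6 deg) raises an error in
`fick_decompose()`; accumulated head rotations are re-orthonormalized
every update; collinear marker triplets and zero-norm direction vectors
are rejected; constant trajectories are ill-posed for the step fit;
echoes shorter than one window yield empty streams with a warning;
constant series have no ACF; non-stationary AR optima are rejected or
penalized.  The cochlear front end (81 Gaussian bands over 20-100 kHz
on the FFT grid, half-wave rectification, a 1-kHz two-stage exponential
low-pass, 100-us windows, 10-us stride, downsample 10, binaural
concatenation to 810 dimensions) uses smoothers with non-negative
impulse responses so features cannot ring negative; the filterbank
family is a documented stand-in, as the reference study names none.

## What the reduced profile can and cannot show

The closed-loop acceptance experiments encode the full-scale
expectations: lower steady-state error and a shorter elevation time
constant under large head rolls than without rolls, an error-surface
minimum that moves towards (0, 0) with the roll condition, and
roll-invariant interaural cue distributions.  At the reduced problem
sizes used by the test suite (64-unit GASSOMs, 150 training targets per
condition, five seeds) the *mechanistic* properties hold — training
raises the reward, trained policies center targets better than
untrained ones, frontally concentrated exposure carves an
error-surface minimum at the front, fixed rolls rotate the surface
exactly as the geometry predicts, and binaurally tuned units emerge —
and the elevation-speed effect of rolls is visible: elevation time
constants under the 30-degree roll condition are reliably shorter than
without rolls, because rolls feed elevation offsets into the strong
binaural channel while the roll-free model must rely on the slower
monaural notch cue.  The *steady-state error* ordering between the two
conditions, by contrast, sits at the edge of what this scale resolves:
with part-trained policies the roll stream still acts partly as motor
and sensory noise, so while the ordering holds for the seed set the
suite runs, repeating the contrast with other seeds can reverse it.
Resolving that ordering decisively requires the full-profile regime,
where the dictionary has concentrated on near-frontal echoes and the
policy exploits roll-synchronous cue rotations.  The test blocks run
the contrast honestly at the documented sizes rather than simulating
the full regime.

## Known limitations

The synthetic HRTF lacks the idiosyncratic spectral detail of measured
bat ears, so monaural elevation cues are cleaner than in reality;
scaled-down training runs reach qualitative, not asymptotic, behavior;
the cochlear-variant comparison and the IC-distribution KL comparisons
require data that is not shipped; no moving targets, pinna movements or
emission directionality are modelled.
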