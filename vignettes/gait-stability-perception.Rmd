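---
title: "Gait stability metrics and the perception of prosthesis control faults: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait stability metrics and the perception of prosthesis control faults: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A powered knee prosthesis driven by an impedance controller can misbehave:
a wrong impedance set applied for a fraction of a second produces a
transient flexion or extension torque fault at the knee. Users feel these
faults — some as a barely noticeable hitch, some as a frank stumble — and
their subjective sense of gait stability shapes how much they trust and
use the device. Objective gait-stability metrics, measurable online from
wearable sensors, are only useful as a surrogate for that subjective
experience if they actually co-vary with it.

`gaitstab` implements the analysis that asks which of eight sagittal-plane
metrics tracks the user's ordinal perception (none / small / medium /
large) of 200 ms knee-level control faults injected during level walking:

* spatial parameters: step length and step width (leg-length normalized);
* stability parameters: margin of stability (MoS) from the extrapolated
  centre of mass, the CoP–CoM inclination angle, and whole-body angular
  momentum about the body CoM;
* postural-control parameters: anterior–posterior CoP progression
  (foot-length normalized) and vertical CoM displacement
  (height-normalized);
* a local measurement: the angular momentum of the residual thigh and
  prosthetic shank about the prosthetic knee ("knee momentum").

## Pipeline

Per trial (one walkway pass): streams are synchronized onto a 100 Hz grid
(the insole rate; the 60 Hz kinematic stream is spline-upsampled), smoothed
with a second-order zero-phase Butterworth low-pass at 7 Hz, segmented into
prosthetic strides from insole heel strikes, and each metric is
time-normalized to a 101-point percent-of-gait-cycle grid. Stance is split
into initial double support (IDS), single support (SS) and terminal double
support (TDS) from the bilateral events.

Per subject: the normal-stride template of each metric is the pointwise
mean of all non-disturbed strides (the stride carrying the fault and the
stride after it are excluded). Each disturbed stride's deviation is the
RMSE against the template over the window from the disturbance onset to
the end of prosthetic stance, divided by the template's excursion
(max − min of the mean): the N-RMSE, a dimensionless, metric-comparable
deviation.

Disturbance conditions (2 types × 2 timings × 3 intensities) are then
merged: intensity-matched permutation SPM compares the A-P CoP
trajectories of condition pairs differing only in timing or only in type,
and cells whose comparisons are predominantly non-significant are joined
(transitive closure). Within the merged groups, Kendall's tau-b relates
N-RMSE to the ordinal perception level, and a quadratic binomial GLM,
`P(perceivable) = logistic(b0 + b1 x + b2 x^2)` with `x` the N-RMSE,
models the probability of a "medium"/"large" report; the quadratic term
lets the probability rise and saturate. A metric is *selected* when a
strict majority of subjects show both a significant tau (two-sided
p < 0.05) and McFadden pseudo-R² > 0.2.

## Model choices that were genuinely open

* **XCoM form.** The extrapolated centre of mass is computed as
  `XCoM = CoM + velCoM * sqrt(l / g)` — Hof's inverted-pendulum scaling
  with `l` the leg length. (Printed renderings of this formula sometimes
  lose the radical; the pendulum eigenfrequency form is the defined one.)
* **Zero-phase filtering.** "Second-order Butterworth at 7 Hz" is applied
  forward–backward, so events and trajectory features keep their timing;
  the price is doubled attenuation (the nominal cutoff is the −6 dB point
  of the combined pass). Event detection runs on the *raw* force signal:
  its loading edges are what define heel strike and toe-off, and smoothing
  them would bias event timing.
* **Resampling.** Streams are upsampled with cubic splines rather than
  linear interpolation; splines are exact on affine signals and keep the
  60→100 Hz error of band-limited gait signals below 10⁻³ of amplitude,
  which linear interpolation cannot guarantee at these rates.
* **Anthropometric table.** Segment masses, CoM offsets and radii of
  gyration come from a packaged Winter/Dempster-style table
  (`inst/extdata/segment_parameters_winter.csv`), scaled by each subject's
  height and mass; thigh+shank lengths are tied to the measured leg
  length, the foot segment to the measured foot length. Per-segment
  overrides accommodate measured prosthetic shank/foot properties.
* **Permutation SPM.** With ~14 strides per condition, random-field-theory
  thresholds are fragile; the family-wise threshold is the 1 − α quantile
  of the permutation distribution of the t-field maximum (exhaustive
  enumeration when cheaper than the permutation budget). Monte-Carlo
  calibration under the null is part of the test suite.
* **Merging rule.** Cells merge when the majority of their three
  intensity-matched comparisons are non-significant — a single 5%
  false positive out of three should not block a merge the other two
  support. The partition applied to the association stage is the one the
  majority of subjects reach.
* **Scalar metrics.** Step length/width have no trajectory; their
  deviation is |value − normal mean| divided by the min–max range of the
  normal per-stride values.
* **Kendall variant.** tau-b with tie correction (ordinal levels are
  heavily tied) and the tie-corrected normal approximation for p. Note
  that tau-b cannot reach 1 when only one of the two variables is tied.
* **Pseudo-R².** McFadden's `1 − LL/LL0`, the convention behind the 0.2
  benchmark.

## The synthetic cohort: what it emulates, and what it does not

No public recording of this protocol exists, so the package ships a
generator that produces every stream the pipeline reads, with ground truth
exposed. One subject walks with a 1.10 s stride (62% stance, 12% double
support), commanded step length 0.55 m and width 0.24 m; sagittal joint
angles are 4-harmonic Fourier series pushed through a 14-segment forward
kinematic chain, with velocities from the analytic chain rule (so
generated positions and velocities are consistent to numerical precision).
Stride-to-stride variability enters as smooth per-stride deviations that
vanish, together with their derivatives, at stride boundaries; trunk sway
gets the largest variability (SD 0.075 rad), reflecting the large postural
variability of transfemoral-amputee gait. Insole force is a double-bump
profile with sharp loading ramps; the CoP progresses heel-to-toe
monotonically.

A control fault is injected as a knee angular-velocity pulse
`A sin(2π(t−t0)/d)` with `d = 200 ms` — a knee-angle bump of
`A d/π` radians that returns to zero — with `A` = 1.5/3.0/4.5 rad/s for
intensities 1–3, positive for flexion and negative for extension faults,
at 3% (IDS) or 25% (SS) of the cycle. Three documented consequences of
real faults are also modelled:

* the prosthetic CoP stagnates late in stance (a braking dip of 0.10
  foot-lengths per intensity unit for flexion, 0.13 for extension, with
  20% lognormal jitter), placed after the latest onset so timing does not
  change the CoP pattern — this is what lets SPM merge timings while
  separating types;
* the user lowers the body slightly (a small, weakly intensity-dependent
  vertical CoM dip);
* the *sound-side* hip answers with a delayed (80 ms), variable-gain
  counter-pulse. This contralateral recovery largely — and
  inconsistently — cancels the fault's signature in whole-body quantities
  (whole-body angular momentum, MoS), which is precisely the mechanism the
  study's discussion offers for why global metrics track perception
  poorly. Without it, whole-body momentum would be an implausibly clean
  readout of the injected pulse.

Perception labels come from a thresholded latent variable: coupling ×
|realized pulse amplitude| + Gaussian noise (SD 0.9), cut at (1.0, 2.4,
4.4). With the default amplitudes this roughly reproduces the observed mix
of reports across levels. Setting the coupling to 0 decouples labels from
gait entirely, which the tests use as a negative control.

What the generator does **not** emulate: temporal gait variability (the
stride period is fixed; time-normalization would largely remove it
anyway), mediolateral dynamics beyond a lateral foot-placement coordinate,
ground-contact dynamics (feet can slip slightly during stance since the
chain is kinematic), soft tissue, IMU drift, and any within-session
learning or strategy change. Passing end-to-end tests therefore shows the
*analysis* recovers the structure a cohort with these couplings carries —
not that real prosthesis data behaves this way.

One entanglement is worth naming: the inclination angle is a deterministic
function of the same CoP and CoM streams that carry the stagnation signal,
so in synthetic cohorts its association with perception sits just at the
selection boundary and can cross it for some subjects. The study likewise
found isolated inclination correlations.

## Numerical choices and degenerate inputs

* Stride intervals are half-open `[HS, next HS)`; a disturbance at a
  boundary belongs to the later stride.
* Events are sub-sample (linearly interpolated) threshold crossings at
  30 N with a 50 ms debounce; a non-alternating pattern after debouncing
  is a hard error, as are stances outside (0.1 s, 2.5 s).
* CoP samples under 30 N of vertical force are masked and excluded from
  templates and N-RMSE windows; template support requires data from at
  least half the strides at a grid point.
* Templates refuse to build from fewer than 20 strides (configurable); a
  zero-excursion template is a hard error at the N-RMSE stage.
* A disturbance onset after stance end (a swing-phase fault) is out of
  protocol and raises an error.
* GLM separation is flagged (`converged = FALSE`), never silently
  reported; constant labels make the correlation an error, not an NA.
* The permutation SPM always includes the observed labelling in its null
  set, so the reported threshold is valid at any permutation budget.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full study geometry —
7 subjects × 168 disturbed passes × 7-stride walkway passes (≈1000 normal
strides per subject against a 360-stride-scale template floor), 2000
permutations per SPM comparison, 1000 Monte-Carlo null simulations for the
SPM calibration, and 200 replicate fits for GLM parameter recovery. These
sizes were chosen to match the study's own scale while keeping a complete
run in the minutes range on a single core.

## Known limitations

* The per-intensity impedance scaling of the real controller is not
  public; the synthetic amplitudes guarantee only ordinal structure.
* The association analysis is strictly per-subject (as in the study);
  there is no mixed-effects pooling.
* Frontal/transverse momenta, joint kinetics, and frequency-domain
  stability measures (Lyapunov exponents, Floquet multipliers, DFA,
  entropy) are out of scope.
* The numeric tau and GLM coefficients of the original cohort are not
  reproducible without the original recordings; what the package
  reproduces is the in-study worked numbers and the structural findings.
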