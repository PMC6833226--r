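---
title: "Modelling spindle positioning under a strong static magnetic field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spindle positioning under a strong static magnetic field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Early cleavage-stage blastomeres of the zebrafish embryo are hundreds of
micrometres across. Their mitotic spindles sit at a size ceiling, so the
job of positioning the spindle at the cell centre and orienting it along
the long axis falls to astral microtubules that span the whole cell. A
homogeneous 9 T static magnetic field (SMF) exerts a torque on every
tubulin dimer through the diamagnetic anisotropy of the alpha-beta axis.
`spindlemag` asks: how do those per-dimer torques propagate to whole
microtubules, then to spindle positioning, and finally to the pace of the
whole embryo's early development?

The package has three layers:

1. **Closed-form magneto-physics** (`dimer_torque()`, through
   `effective_pulling_force()`): exact expressions, SI units.
2. **A Monte Carlo simulator** (`simulate_spindle()` and friends):
   stochastic astral-microtubule dynamics driving overdamped rigid-body
   motion of the spindle in a planar elliptical cell.
3. **Relaxation and delay analysis** (`extract_relaxation_time()`,
   `accumulate_delay()`): relaxation times from trajectories, and
   per-cycle slowdown accumulated over the cleavage schedule.

## The magneto-physics layer

All expressions share one amplitude, the orientation energy scale
$A = \Delta\chi B^2 / 2\mu_0$, with $\Delta\chi = 1.243\times10^{-32}$
m$^3$ per dimer. At 9 T, $A \approx 4.0\times10^{-25}$ J, which is about
$10^{-4}\,k_BT$ at 301.65 K (the 28.5 °C rearing temperature): a single
dimer barely notices the field.

* Torque on one dimer: $M_0 = A\sin 2\theta$, period $\pi$.
* Orientation energy: $E = A\sin^2\theta$; free dimers follow the
  Boltzmann density $\propto e^{-E/k_BT}$, normalized numerically on the
  planar support $[-\pi/2, \pi/2)$ (a spherical, $\sin\theta$-weighted
  option exists behind a flag; the simulator is planar, so planar is the
  default).
* Polymerization rate: $v(\theta) = v_0 e^{-A\sin^2\theta/k_BT}$ with
  $v_0 = 0.125$ µm/s. Growth parallel to the field proceeds at exactly
  $v_0$; perpendicular growth is slower by the factor
  $e^{-9.6\times10^{-5}}$ — a negligible change.
* Rigid-rod torque: a length-$L$ microtubule carries $13L/d_0$ dimers
  ($d_0 = 8$ nm), so $M = (13L/d_0)\,A\sin 2\theta$; balancing against
  rotational drag $\xi L^2/2$ gives a rotation rate of order $10^{-8}$
  rad/s — also negligible.
* Bending: the torque is distributed along the rod, giving a cantilever
  (clamped at the pole) the deflection
  $\omega(x) \propto \tfrac12 Lx^2 - \tfrac16 x^3$ with tip deflection
  $\omega_{max} \propto L^3 B^2$. At 50 µm this is 0.8 µm; at 200–300 µm
  (cell-spanning lengths) it reaches tens of micrometres. **Bending is
  the only channel that becomes large**, because it integrates the tiny
  per-dimer torque twice along the length.
* Force reduction: a bent rod of arc length $L$ and tip deflection
  $\omega_{max}$ spans the chord $\sqrt{L^2 - \omega_{max}^2}$, so a
  pulling force along it is reduced to
  $f^* = f_c\sqrt{L^2-\omega_{max}^2}/L$. We divide by $L$ to keep the
  expression dimensionally a force with $f^* = f_c$ for an unbent rod.

Two printed constants required a units decision. A bending rigidity of
33.12 pN m$^2$ would make SMF bending immeasurable ($\sim10^{-10}$ µm),
which is inconsistent with bending being the dominant channel; we read
it as 33.12 pN µm$^2$ = $3.312\times10^{-23}$ N m$^2$, the standard
magnitude of microtubule flexural rigidity. Similarly the drag "1 pN s
/nm" per unit length is taken as $\xi = 10^{-3}$ N s/m$^2$ so the
rotation-rate formula yields rad/s. Both are `physical_constants()`
fields and can be overridden.

The small-deformation formula can predict $\omega_{max} > L$ for long
rods at 9 T; `clamp_deflection()` caps the magnitude at $0.99L$ before
the chord projection (which is only real-valued below $L$) and flags
clamped microtubules.

## The simulator

A planar ellipse (default 600 × 300 µm, the first-cleavage blastodisc)
contains a rigid spindle: two poles at `center ± s(cos α, sin α)` with
fixed half-separation `s = 30` µm. Each pole nucleates `n_mt` astral
microtubules that grow radially with two-state dynamic instability and
exert three forces:

* a cytoplasmic pull `alpha_cyto · L` along the microtubule (length-
  dependent pulling by cytoplasmic motors) — this is the centering and
  orienting engine;
* at cortex contacts, a polymerization push `f_push` antiparallel to
  growth;
* at cortex contacts, a dynein pull `f_dyn` with binding probability
  `p_bind` per step.

Forces transmit to the spindle at the anchoring pole; the spindle obeys
overdamped dynamics with drags `Gamma_t`, `Gamma_r`. With the field on,
the three SMF channels modulate the microtubules: growth speed by
$v(\theta)/v_0$, direction by the rotation rate, and every pulling
magnitude by the chord factor from the deflection at that length and
angle. The rigid-rod magnetic torques also act on the spindle
orientation directly.

### Design choices that mattered

**Rescue-dominated dynamic instability.** The defaults
(`f_cat` = 0.05 s⁻¹, `f_res` = 0.5 s⁻¹ with `v_g` = 0.125, `v_s` = 0.25
µm/s) put tips in the unbounded-growth regime: microtubules reach the
cortex and track it with shallow shortening excursions of mean depth
`v_s/f_res` ≈ 12.5 µm. Length-dependent pulling can only centre the
spindle if lengths reflect distances to the cortex, which requires
cell-spanning microtubules; bounded-regime parameters (mean length
`v_g/f_cat` far below the cell size) produce no centering at all. The
force coefficients and switching rates are artifact choices of this
package — the published reference model's constants are not reprinted
anywhere we can quote — and all are configurable.

**Stratified nucleation with template renucleation.** Nucleation
directions are jittered equal-spaced fans per pole (marginally uniform
on $[0, 2\pi)$), and a fully depolymerized microtubule regrows along its
nucleation direction. With independent uniform directions (or fresh
directions at renucleation), a run keeps a quenched $O(1/\sqrt{n})$
angular imbalance whose torque is as large as the restoring torque: the
spindle strands tens of micrometres off centre and misorients by
30–40°. The stratified, template-anchored fan emulates the dense,
near-isotropic aster of a real cell at a tractable microtubule count.

**Bending acts on force magnitude, not direction, by default.** The
force-reduction law is a statement about magnitude. We also implemented
the stronger reading in which the pull direction tilts along the bent
chord toward the field axis (`effects["deviation"]`), but it reverses
the orientation effect: with the tilt on, orientation relaxes *faster*
under the field (ratio ≈ 0.54), contradicting the qualitative behaviour
the model exists to produce. The default therefore scales magnitudes
only; the tilt remains available for exploration.

**Drag scales with the aster.** What moves is the spindle together with
its cell-spanning astral array, so the translational drag scales as
`a/300` and the rotational drag as `(a/300)^3` from their reference
values at the first-cleavage geometry. This is what makes positioning
and orientation slower in larger cells; with size-independent drags the
relaxation time would be nearly scale-free, because the pulling
stiffness of length-proportional forces is itself scale-free.

**Time acceleration.** At the literal $v_0$, growing a 300 µm aster
takes ~40 min of simulated time and positioning hours. `sim_config()`
carries a dimensionless `speedup` (default 25) multiplying the polymer
speeds and the field-induced rotation rate. All cross-condition
comparisons are made on normalized time $t^* = t/\tau$ or as ratios of
relaxation times, where the factor cancels; absolute seconds in the
trajectories are not the claim.

**Numerical details.** Time step 0.5 s (switching probabilities
`f·dt` ≤ 0.25; the step function refuses `f·dt > 1`). Cortex contact is
a tip within 0.5 µm of the boundary; tips beyond it are truncated by an
exact ray–ellipse intersection. Paired field/control runs share seeds
and draw identical random-number streams (switching, renucleation and
dynein draws are made unconditionally each step), so the field enters
as a purely deterministic perturbation — common random numbers make the
paired τ ratios far less noisy than independent ensembles would.
A derived-seed rule (`child_seed()`) fans one user seed into per-run
streams.

## Relaxation and delay

`extract_relaxation_time()` fits $y = y_0 e^{-t/\tau}$ by weighted least
squares on $\log y$ (weights $\propto y$, the variance stabilization for
multiplicative noise), with two guards: the fit window stops at the
first crossing below 10 % of the initial value, so the late-time
fluctuation plateau of a stochastic run does not bias τ; and a fitted τ
more than twenty times the observation window is reported as
`no_relaxation_error` (a constant series decays only by rounding). If
the fit degenerates the estimator falls back to the interpolated
1/e-crossing time. On synthetic noisy decays (CV 1 %, 200 points) the
estimator recovers τ with < 0.01 % mean bias and < 1 % per-run error.

`accumulate_delay()` turns per-cycle slowdown ratios into minutes: each
cycle of duration $T$ with ratio $r$ needs $(r-1) \cdot f \cdot T$ extra
minutes, where $f$ is the fraction of the cycle spent positioning
(default 1.0 — the upper bound; the claim is the ordering, not the
minute count, and $f$ is exposed for sensitivity analysis). The default
schedule is the zebrafish one: a first cycle of 37.5 min (midpoint of
30–45 min) followed by 8 synchronous 15-min cycles, the cell shrinking
by $2^{-1/3}$ linearly per cycle (volume halving).

## What the synthetic generator does and does not emulate

`make_decay_series()`, `make_init_condition_sweep()` and
`make_paired_field_ensemble()` generate every input the pipeline needs:
noisy exponentials with known τ (ground truth for recovery tests),
random initial spindle placements uniform in the concentric half-scale
ellipse with uniform orientations, and field/control configuration
pairs on shared seeds. They reproduce the statistical structure the
simulator assumes — not real data. In particular the model is planar,
the cell is a rigid ellipse with no yolk or cytoplasmic flow, there are
no chromosomes or centrosome duplication, thermal bending fluctuations
of microtubules are ignored (only the deterministic SMF deflection is
kept), and the spindle is a rigid two-pole body. Passing tests
demonstrate the internal consistency of this mechanism, not a
quantitative prediction for a real embryo.

## Problem sizes

The behavioural analyses use 20-run ensembles with 50 microtubules per
pole and 1500 s of simulated time (about five positioning relaxation
times) for the first-cleavage cell, 800 s for the half-scale cell —
sizes at which the ensemble-mean curves are smooth and the paired
ratios stable to the second decimal while a full analysis completes in
minutes on a laptop. `analysis/01–03` and `scripts/acceptance.R` print
every number they compute.

## Known limitations

* Absolute times depend on the artifact force/drag constants and the
  `speedup` convention; only normalized curves and ratios are
  meaningful.
* The field-direction geometry inside the magnet bore relative to the
  cleavage plane is not pinned down by the exposure setup; the default
  puts the field along the cell's short axis, and the choice is
  configurable (`field_spec(direction_angle =)`). Slowdowns are
  direction-dependent.
* The orientation relaxation of the half-scale cell is much faster than
  its positioning relaxation (the rotational drag scales down as the
  cube); its τ ratio is correspondingly closer to 1.
* The delay accumulator applies measured ratios per cycle; we simulate
  two geometries (first cleavage and half scale) and reuse the latter
  for cycles 2–9 rather than simulating all nine sizes.
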