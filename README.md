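# spindlemag

Mechanical model of how a strong static magnetic field (SMF) perturbs
microtubules and thereby slows mitotic spindle positioning and
orientation in large embryonic blastomeres — and of how that per-cycle
slowdown accumulates into a developmental delay of the whole embryo.

Early zebrafish blastomeres are hundreds of micrometres across; their
spindles are positioned and oriented by cell-spanning astral
microtubules. A homogeneous 9 T field couples to the diamagnetic
anisotropy of tubulin (Δχ = 1.243 × 10⁻³² m³ per dimer), producing a
per-dimer torque M₀ = ΔχB²/(2μ₀)·sin 2θ of only ~10⁻⁴ k_BT — yet a
microtubule of length L carries 13L/d₀ dimers, and the distributed
torque bends it like a cantilever with tip deflection ω_max ∝ L³B².
For cell-spanning microtubules the deflection reaches tens of
micrometres, and the pulling force transmitted along the bent rod drops
by the chord projection f* = f_c·√(L² − ω²_max)/L. The package
implements:

* **Closed-form magneto-physics** — dimer torque and orientation
  energy, the Boltzmann orientation density, the direction-dependent
  polymerization rate v(θ) = v₀·exp(−ΔχB²sin²θ/2μ₀k_BT), rigid-rod
  torque and rotation rate, Euler–Bernoulli deflection under the
  distributed torque, and the chord-projected force reduction.
* **A seeded Monte Carlo simulator** — astral microtubules with
  dynamic instability in a planar elliptical cell (600 × 300 µm at
  first cleavage), cytoplasmic length-dependent pulling, cortical
  pushing and dynein pulling, driving overdamped rigid-body motion of
  the spindle; all three SMF channels switchable for ablation.
* **Relaxation & delay analysis** — exponential relaxation times τ_d
  (positioning) and τ_α (orientation) from trajectories, normalized
  time t* = t/τ, and accumulation of per-cycle slowdown over the
  zebrafish cleavage schedule (37.5 min first cycle + 8 × 15 min).

## Worked example

```r
library(spindlemag)

# how strongly does 9 T bend a 50-um microtubule at 45 deg to the field?
prof <- deflection(50e-6, pi/4, field_spec(9))
prof$omega_max * 1e6
#> [1] 0.8189702

# paired control / 9 T ensembles (20 runs each, common random numbers)
init <- spindle_state(c(60, 30), 0.5)          # displaced, misoriented
cfg  <- sim_config(t_max = 1500, n_mt = 50, seed = 1, ensemble_n = 20)
cmp  <- compare_field_conditions(init, cell_geometry(), cfg)
cmp$summaries$B0
#> relaxation_summary: tau_d = 303 s, tau_alpha = 364 s (20 runs)
c(cmp$tau_ratio_d, cmp$tau_ratio_alpha)
#> [1] 1.128863 1.056220

# accumulate the slowdown over the early cleavage schedule
ratios <- c(cmp$tau_ratio_d, rep(1.007, 8))    # half-scale ratio for cycles 2-9
accumulate_delay(ratios, cleavage_schedule())
#> delay_report: 9 cycles, cumulative delay 5.67 min
```

Both relaxation-time ratios exceed 1: the field slows positioning by
~13 % and orientation by ~6 % in the first-cleavage cell, and channel
ablation shows microtubule *bending* carries essentially the whole
effect (the polymerization and rotation channels are ~10⁻⁴
perturbations). The control ensemble ends centred (offset < 1 µm,
|α| ≈ 1.3°), and relaxation is slower in the 600 × 300 µm cell than in
a half-scale cell.

## Analysis workflow

Numbered drivers under `analysis/` run the full study and write tables
to `results/`:

```sh
Rscript analysis/01_magnetophysics.R        # angle/length tables, deflection profile
Rscript analysis/02_simulate_ensembles.R    # paired ensembles, t* curves, manifest
Rscript analysis/03_relaxation_delay.R      # ablation, size effect, delay table
```

Configuration is YAML-based (`load_config()`, example in
`inst/extdata/first_cleavage_9T.yaml`); trajectories round-trip through
CSV at full precision; every stochastic stage is seeded.

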