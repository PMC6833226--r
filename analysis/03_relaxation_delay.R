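#!/usr/bin/env Rscript
# Channel ablation, cell-size dependence and the whole-embryo delay
# estimate. Quantifies which field effect (polymerization, rotation,
# bending) carries the slowdown, confirms larger cells relax more
# slowly, and accumulates the per-cycle slowdown over the early
# cleavage schedule.
#
# Usage: Rscript analysis/03_relaxation_delay.R [seed]

suppressPackageStartupMessages(library(spindlemag))
dir.create("results", showWarnings = FALSE)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

init <- spindle_state(c(60, 30), 0.5)
geom <- cell_geometry()
base_cfg <- function(...) {
  args <- utils::modifyList(list(t_max = 1500, n_mt = 50, seed = seed,
                                 ensemble_n = 20), list(...))
  do.call(sim_config, args)
}
seeds <- child_seed(seed, 1:20)

cat("ablation: which field channel carries the slowdown?\n")
ens_b0 <- run_ensemble(init, geom, base_cfg(), seeds = seeds)
tau0 <- relaxation_summary(ens_b0)
one_channel <- function(poly, rotation, bending) {
  cfg <- base_cfg(field = field_spec(9),
                  effects = c(poly = poly, rotation = rotation,
                              bending = bending, deviation = FALSE))
  relaxation_summary(run_ensemble(init, geom, cfg, seeds = seeds))
}
ab <- list(bending = one_channel(FALSE, FALSE, TRUE),
           rotation = one_channel(FALSE, TRUE, FALSE),
           poly = one_channel(TRUE, FALSE, FALSE))
ablation <- data.frame(
  channel = names(ab),
  tau_d_s = vapply(ab, function(s) s$tau_d, numeric(1)),
  delta_tau_d_s = vapply(ab, function(s) s$tau_d - tau0$tau_d, numeric(1)),
  tau_ratio_d = vapply(ab, function(s) s$tau_d / tau0$tau_d, numeric(1)))
utils::write.csv(ablation, "results/03_ablation.csv", row.names = FALSE)
print(ablation, row.names = FALSE)
cat("  -> microtubule bending carries essentially the whole slowdown;\n")
cat("     rotation and polymerization channels are ~1e-4 effects.\n\n")

cat("cell-size dependence of the relaxation time (control condition):\n")
sizes <- data.frame(scale = c(1, 0.5))
sizes$tau_d_s <- NA; sizes$tau_alpha_s <- NA
for (i in seq_len(nrow(sizes))) {
  sc <- sizes$scale[i]
  cfg <- base_cfg(t_max = if (sc < 1) 800 else 1500)
  s <- relaxation_summary(run_ensemble(
    spindle_state(c(60, 30) * sc, 0.5),
    cell_geometry(300 * sc, 150 * sc), cfg, seeds = seeds))
  sizes$tau_d_s[i] <- s$tau_d
  sizes$tau_alpha_s[i] <- s$tau_alpha
}
utils::write.csv(sizes, "results/03_size_effect.csv", row.names = FALSE)
print(sizes, row.names = FALSE)
cat("  -> the first-cleavage cell relaxes more slowly than the\n")
cat("     half-scale (later-cycle) cell.\n\n")

cat("whole-embryo delay over the cleavage schedule:\n")
cmp_big <- compare_field_conditions(init, geom, base_cfg())
cmp_small <- compare_field_conditions(
  spindle_state(c(30, 15), 0.5), cell_geometry(150, 75),
  base_cfg(t_max = 800, seed = seed + 1L))
sched <- cleavage_schedule()
ratios <- c(cmp_big$tau_ratio_d,
            rep(cmp_small$tau_ratio_d, sched$n_synchronous_cycles))
report <- accumulate_delay(ratios, sched)
delay_tab <- data.frame(cycle = seq_along(ratios),
                        duration_min = cycle_durations(sched),
                        tau_ratio = ratios,
                        extra_min = report$per_cycle_extra_min)
utils::write.csv(delay_tab, "results/03_delay_per_cycle.csv",
                 row.names = FALSE)
print(delay_tab, row.names = FALSE)
cat(sprintf("cumulative developmental delay: %.1f min over %d cycles\n",
            report$cumulative_delay_min, length(ratios)))
cat("(orderings, not absolute minutes, are the claim: per-cycle\n")
cat(" slowdown ratios > 1 accumulate into a whole-embryo delay)\n")
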