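#!/usr/bin/env Rscript
# Closed-form magneto-physics of microtubules at the 9 T exposure
# condition: how strongly does the field torque, slow, rotate and bend a
# microtubule? Writes per-angle and per-length tables under results/.
#
# Headline numbers this script reports:
#   - the dimer torque amplitude (~4.0e-25 N m, ~1e-4 kBT of orientation
#     energy: single dimers barely feel the field),
#   - the perpendicular polymerization slowdown (a 9.6e-5 relative
#     effect: essentially negligible),
#   - the rigid-rod rotation rate (~1.3e-8 rad/s at 100 um: negligible),
#   - the tip deflection (0.8 um at 50 um length, growing as L^3 -- the
#     one channel that becomes large for cell-spanning microtubules).

suppressPackageStartupMessages(library(spindlemag))
dir.create("results", showWarnings = FALSE)

consts <- physical_constants()
f9 <- field_spec(9)

theta <- seq(0, pi, length.out = 181)
angle_tab <- data.frame(
  theta_rad = theta,
  dimer_torque_Nm = dimer_torque(theta, f9, consts),
  orientation_energy_J = dimer_orientation_energy(theta, f9, consts),
  orientation_pdf_1_rad = dimer_orientation_pdf(
    pmin(pmax(theta - pi / 2, -pi / 2), pi / 2 - 1e-9), f9, consts),
  polymerization_rate_um_s = polymerization_rate(theta, f9, consts) * 1e6,
  rotation_rate_rad_s_L100 = mt_rotation_rate(1e-4, theta, f9, consts)
)
utils::write.csv(angle_tab, "results/01_angle_dependence.csv",
                 row.names = FALSE)

L_um <- c(10, 25, 50, 100, 200, 300)
len_tab <- data.frame(
  L_um = L_um,
  mt_torque_Nm = mt_torque(L_um * 1e-6, pi / 4, f9, consts),
  omega_max_um = vapply(L_um, function(L)
    deflection(L * 1e-6, pi / 4, f9, consts)$omega_max * 1e6, numeric(1))
)
len_tab$omega_clamped_um <- clamp_deflection(len_tab$omega_max, L_um)$omega
len_tab$pull_ratio <- effective_pulling_force(1, L_um,
                                              len_tab$omega_clamped_um)
utils::write.csv(len_tab, "results/01_length_dependence.csv",
                 row.names = FALSE)

prof <- deflection(50e-6, pi / 4, f9, consts)
utils::write.csv(as.data.frame(prof), "results/01_deflection_profile.csv",
                 row.names = FALSE)

cat("Magneto-physics at 9 T:\n")
cat(sprintf("  dimer torque amplitude:        %.4g N m (%.2g kBT)\n",
            dimer_torque(pi / 4, f9, consts),
            dimer_torque(pi / 4, f9, consts) / (consts$kB * consts$T_abs)))
cat(sprintf("  perpendicular growth slowdown: %.3g (relative)\n",
            1 - polymerization_rate(pi / 2, f9, consts) / consts$v0))
cat(sprintf("  rotation rate at L = 100 um:   %.3g rad/s\n",
            mt_rotation_rate(1e-4, pi / 4, f9, consts)))
cat(sprintf("  tip deflection at L = 50 um:   %.3g um (ratio %.3g of L)\n",
            prof$omega_max * 1e6, prof$omega_max * 1e6 / 50))
cat("  -> bending is the only channel that grows large (as L^3) for\n")
cat("     the cell-spanning astral microtubules of the first cleavage.\n")
cat("Tables written to results/01_*.csv\n")
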