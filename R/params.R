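# Parameter containers for the Monte Carlo spindle simulator. Simulator
# units: micrometre, piconewton, second. Defaults for the dynamic
# instability and force coefficients are artifact choices of this package
# (the reference spindle-positioning model's constants are not reprinted
# anywhere we can cite numbers from); all are configurable.

#' Microtubule dynamic instability parameters
#'
#' Two-state (growing/shrinking) tip dynamics: growth at `v_g`, shrinkage
#' at `v_s`, with catastrophe and rescue as Poisson switches.
#'
#' @param v_g Growth speed, um/s. Defaults to the zero-field
#'   polymerization speed `v0` (0.125 um/s).
#' @param v_s Shrinkage speed, um/s.
#' @param f_cat Catastrophe rate, 1/s.
#' @param f_res Rescue rate, 1/s. The defaults sit in the rescue-dominated
#'   (unbounded-growth) regime, so astral microtubules span the cell and
#'   track the cortex with shallow (~`v_s/f_res`) shortening excursions --
#'   the regime the length-dependent centering mechanism requires in
#'   large blastomeres.
#' @return A `dynamic_instability_params` object.
#' @export
dynamic_instability_params <- function(v_g = 0.125, v_s = 0.25,
                                       f_cat = 0.05, f_res = 0.5) {
  vals <- list(v_g = v_g, v_s = v_s, f_cat = f_cat, f_res = f_res)
  for (nm in names(vals)) stop_unless_number(vals[[nm]], nm, nonneg = TRUE)
  structure(vals, class = "dynamic_instability_params")
}

#' Force coefficients acting on astral microtubules
#'
#' @param alpha_cyto Cytoplasmic-motor pulling coefficient, pN per um of
#'   microtubule length (length-dependent pulling).
#' @param f_push Cortical polymerization pushing force, pN.
#' @param f_dyn Cortical dynein pulling force, pN.
#' @param p_bind Dynein binding probability per cortex contact per step.
#' @param Gamma_t Translational drag of the spindle-plus-aster array,
#'   pN s/um, specified for an aster of reference extent 300 um
#'   (first-cleavage semi-major axis). The simulator scales it by
#'   `a / 300` (Stokes drag of the array grows with its linear size).
#' @param Gamma_r Rotational drag, pN s um, at the same reference extent;
#'   scaled by `(a / 300)^3`.
#' @return A `force_params` object.
#' @export
force_params <- function(alpha_cyto = 0.01, f_push = 1, f_dyn = 2,
                         p_bind = 0.1, Gamma_t = 100, Gamma_r = 1e5) {
  vals <- list(alpha_cyto = alpha_cyto, f_push = f_push, f_dyn = f_dyn,
               p_bind = p_bind, Gamma_t = Gamma_t, Gamma_r = Gamma_r)
  for (nm in names(vals)) stop_unless_number(vals[[nm]], nm, nonneg = TRUE)
  if (p_bind > 1) abort_domain("`p_bind` must be a probability in [0, 1]")
  structure(vals, class = "force_params")
}

#' Simulation configuration
#'
#' @param dt Time step, s.
#' @param t_max Simulated duration, s (`>= dt`); the default covers
#'   roughly five positioning relaxation times of the first-cleavage cell.
#' @param n_mt Microtubules nucleated per spindle pole.
#' @param seed Integer RNG seed; a fixed seed makes the run
#'   bit-reproducible.
#' @param field A [field_spec()] (default: no field).
#' @param ensemble_n Number of runs in an ensemble.
#' @param speedup Dimensionless time-acceleration factor applied to
#'   polymer speeds (`v_g`, `v_s`) and the field-induced rotation rate, so
#'   that positioning completes within ~1e3 simulated seconds. Comparisons
#'   across conditions are made on normalized time t*, where this factor
#'   cancels.
#' @param stride Record every `stride`-th step in the trajectory.
#' @param cortex_tol Tip-to-boundary distance counted as cortex contact, um.
#' @param effects Named logical vector switching the SMF channels:
#'   `poly` (direction-dependent polymerization), `rotation` (rigid-rod
#'   torque and rotation), `bending` (deflection and chord-projected force
#'   reduction) and `deviation` (tilt of the pull direction along the bent
#'   chord; off by default -- the force-reduction law is a statement about
#'   magnitude, and the tilt reverses the orientation slowdown). Used for
#'   ablation studies.
#' @return A `sim_config` object.
#' @export
sim_config <- function(dt = 0.5, t_max = 1500, n_mt = 100, seed = 1L,
                       field = field_spec(0), ensemble_n = 20,
                       speedup = 25, stride = 1L, cortex_tol = 0.5,
                       effects = c(poly = TRUE, rotation = TRUE,
                                   bending = TRUE, deviation = FALSE)) {
  stop_unless_number(dt, "dt", positive = TRUE)
  stop_unless_number(t_max, "t_max", positive = TRUE)
  if (t_max < dt) abort_domain("`t_max` must be >= `dt`")
  stop_unless_number(n_mt, "n_mt", positive = TRUE)
  if (n_mt < 1 || n_mt != round(n_mt)) abort_domain("`n_mt` must be an integer >= 1")
  stop_unless_number(seed, "seed")
  stop_unless_number(speedup, "speedup", positive = TRUE)
  stop_unless_number(stride, "stride", positive = TRUE)
  stop_unless_number(cortex_tol, "cortex_tol", nonneg = TRUE)
  field <- as_field_spec(field)
  eff <- c(poly = TRUE, rotation = TRUE, bending = TRUE, deviation = FALSE)
  eff[names(effects)] <- as.logical(effects)
  structure(list(dt = dt, t_max = t_max, n_mt = as.integer(n_mt),
                 seed = as.integer(seed), field = field,
                 ensemble_n = as.integer(ensemble_n), speedup = speedup,
                 stride = as.integer(stride), cortex_tol = cortex_tol,
                 effects = eff),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: dt %g s, t_max %g s, %d MT/pole, seed %d, B %g T, speedup %g\n",
    x$dt, x$t_max, x$n_mt, x$seed, x$field$B, x$speedup))
  invisible(x)
}
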