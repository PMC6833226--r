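# Monte Carlo simulator of spindle positioning and orientation in a planar
# elliptical cell. Astral microtubules are nucleated at the two spindle
# poles, grow radially with dynamic instability, and exert (i) a
# cytoplasmic pulling force proportional to their length, (ii) a cortical
# pushing force by polymerization, and (iii) a cortical dynein pulling
# force bound stochastically. Together these centre the spindle and orient
# it along the long axis. A static field perturbs all three microtubule
# properties (polymerization rate, rotation, bending) through the
# closed-form magneto-physics.
#
# Internal representation of a microtubule ensemble: a plain list of
# parallel vectors (cheap to mutate inside the step loop). Lengths in um,
# forces in pN, time in s.

mt_ensemble <- function(pole_id, psi, L, growing, at_cortex, clamped_bend) {
  structure(list(pole_id = pole_id, psi = psi, L = L, growing = growing,
                 at_cortex = at_cortex, clamped_bend = clamped_bend),
            class = "mt_ensemble")
}

#' @export
as.data.frame.mt_ensemble <- function(x, ...) {
  data.frame(pole_id = x$pole_id, psi = x$psi, L = x$L,
             state = ifelse(x$growing, "growing", "shrinking"),
             at_cortex = x$at_cortex, clamped_bend = x$clamped_bend)
}

#' Nucleate a fresh astral microtubule ensemble
#'
#' `n_mt` microtubules per pole, initial length zero, all growing. Growth
#' directions are drawn per pole as a jittered equal-spaced fan: each
#' direction is `2 pi (i + u_pole) / n_mt`, with one uniform rotation
#' `u_pole` per pole. Marginally every direction is uniform on
#' \[0, 2 pi), but the stratification emulates the dense, near-isotropic
#' angular coverage of a real aster at a tractable microtubule count
#' (plain independent draws leave an O(1/sqrt(n)) angular imbalance that
#' displaces the force fixed point by tens of micrometres). Uses the
#' current RNG stream; seed the stream (or run through
#' [simulate_spindle()]) for reproducibility.
#'
#' @param state A [spindle_state()].
#' @param cfg A [sim_config()]; `cfg$n_mt` microtubules per pole.
#' @return An `mt_ensemble` with `2 * n_mt` microtubules.
#' @export
nucleate_ensemble <- function(state, cfg) {
  n_p <- cfg$n_mt
  psi <- unlist(lapply(1:2, function(p)
    2 * pi * (seq_len(n_p) - 1 + stats::runif(1)) / n_p))
  n <- 2L * n_p
  mt_ensemble(pole_id = rep(1:2, each = n_p),
              psi = psi,
              L = numeric(n),
              growing = rep(TRUE, n),
              at_cortex = rep(FALSE, n),
              clamped_bend = rep(FALSE, n))
}

# Tip deflection magnitude (um) of microtubules of length L_um at angle
# theta to the field, clamped below the length; vectorized.
tip_deflection_um <- function(L_um, theta, field, consts, clamp_frac = 0.99) {
  K <- 13 * consts$delta_chi * field$B^2 /
    (2 * consts$d0 * consts$mu0 * consts$EI)      # 1/m^2
  w_um <- abs(K * sin(2 * theta)) * (L_um * 1e-6)^3 / 3 * 1e6
  clamp_deflection(w_um, pmax(L_um, .Machine$double.eps), clamp_frac)
}

#' Advance every microtubule by one time step
#'
#' Growing tips elongate at the (field-modulated) polymerization speed;
#' shrinking tips shorten at `v_s`; catastrophe and rescue are Bernoulli
#' events with probabilities `f_cat dt` and `f_res dt`. A fully
#' depolymerized microtubule renucleates immediately and regrows along its
#' nucleation template direction, keeping the aster isotropic. When a
#' field is on, free (non-cortex) microtubules rotate
#' toward the field at the rigid-rod rotation rate. Tips beyond the cell
#' boundary are truncated to it and flagged as cortex contacts.
#'
#' @param mts An `mt_ensemble`.
#' @param poles 2 x 2 matrix of pole positions (um), rows indexed by
#'   `pole_id`.
#' @param geom A [cell_geometry()].
#' @param di [dynamic_instability_params()] (already time-scaled if a
#'   speedup is in use).
#' @param field A [field_spec()].
#' @param consts [physical_constants()].
#' @param dt Time step, s.
#' @param effects Named logical vector (`poly`, `rotation`) switching the
#'   field channels.
#' @param rotation_scale Multiplier on the field-induced rotation rate
#'   (the time-acceleration factor).
#' @param cortex_tol Contact tolerance, um.
#' @param draws Optional list with uniform draws `u_switch` (length `n`);
#'   drawn internally when `NULL`. Supplying draws keeps paired runs on
#'   common random numbers.
#' @return The advanced `mt_ensemble`.
#' @export
step_microtubule <- function(mts, poles, geom, di, field, consts, dt,
                             effects = c(poly = TRUE, rotation = TRUE),
                             rotation_scale = 1, cortex_tol = 0.5,
                             draws = NULL) {
  if (dt <= 0) abort_domain("`dt` must be positive")
  if (di$f_cat * dt > 1 || di$f_res * dt > 1)
    abort_timestep(sprintf(
      "switching probability exceeds 1 at dt = %g s; reduce the time step", dt))
  n <- length(mts$L)
  if (is.null(draws))
    draws <- list(u_switch = stats::runif(n))

  # catastrophe / rescue
  p_switch <- ifelse(mts$growing, di$f_cat, di$f_res) * dt
  flip <- draws$u_switch < p_switch
  growing <- xor(mts$growing, flip)

  # elongation / shortening; Eq-2.4-style modulation of the growth speed
  theta <- mts$psi - field$direction_angle
  v_grow <- di$v_g
  if (field$B > 0 && isTRUE(effects[["poly"]]))
    v_grow <- di$v_g * exp(-dimer_orientation_energy(theta, field, consts) /
                             (consts$kB * consts$T_abs))
  L <- mts$L + ifelse(growing, v_grow, -di$v_s) * dt

  # a fully depolymerized microtubule renucleates immediately and regrows
  # along its nucleation template (same direction). Redrawing a fresh
  # uniform direction instead permanently scrambles the stratified fan:
  # each run then keeps a quenched O(sqrt(n)) angular imbalance whose
  # torque rivals the restoring torque and strands the spindle off-centre.
  gone <- L <= 0
  psi <- mts$psi
  at_cortex <- mts$at_cortex
  if (any(gone)) {
    L[gone] <- 0
    growing[gone] <- TRUE
    at_cortex[gone] <- FALSE
  }

  # rigid-rod rotation toward the field (free microtubules only)
  if (field$B > 0 && isTRUE(effects[["rotation"]])) {
    free <- !at_cortex & L > 0
    if (any(free)) {
      rate <- mt_rotation_rate(pmax(L[free], 1) * 1e-6,
                               psi[free] - field$direction_angle,
                               field, consts)
      psi[free] <- psi[free] - rate * rotation_scale * dt
    }
  }

  # truncate at the cortex
  px <- poles[mts$pole_id, 1]
  py <- poles[mts$pole_id, 2]
  reach <- ray_to_boundary(px, py, psi, geom)
  L <- pmin(L, reach)
  at_cortex <- L >= reach - cortex_tol

  mt_ensemble(mts$pole_id, psi, L, growing, at_cortex, mts$clamped_bend)
}

#' Net force and torque exerted on the spindle by its microtubules
#'
#' Per microtubule: a cytoplasmic pull of magnitude `alpha_cyto * L`
#' directed along the chord from its pole to its (possibly deflected) tip;
#' for cortex contacts, a polymerization push of `f_push` antiparallel to
#' the growth direction and, with probability `p_bind`, a dynein pull of
#' `f_dyn` along it. With the field on and the bending channel enabled,
#' every pulling magnitude is scaled by the chord projection
#' `sqrt(L^2 - omega_max^2)/L` and the pull direction tilts toward the
#' deflected tip; the rigid-rod magnetic torques additionally act on the
#' spindle orientation. Forces are transmitted at the anchoring pole, so
#' torques use the pole offset from the spindle centre as lever arm.
#'
#' @param state A [spindle_state()].
#' @param mts An `mt_ensemble`.
#' @param fp A [force_params()].
#' @param field A [field_spec()].
#' @param consts [physical_constants()].
#' @param effects Named logical vector (`bending`, `rotation`,
#'   `deviation`); `deviation` controls whether the pull direction tilts
#'   along the bent chord or only the magnitude is reduced.
#' @param u_bind Optional uniform draws (length `n`) deciding dynein
#'   binding; drawn internally when `NULL`.
#' @return List with `force` (pN, length-2) and `torque` (pN um, scalar,
#'   counter-clockwise positive).
#' @export
net_wrench <- function(state, mts, fp, field = field_spec(0),
                       consts = physical_constants(),
                       effects = c(bending = TRUE, rotation = TRUE,
                                   deviation = FALSE),
                       u_bind = NULL) {
  n <- length(mts$L)
  if (n == 0L) return(list(force = c(0, 0), torque = 0))
  if (is.null(u_bind)) u_bind <- stats::runif(n)

  poles <- spindle_poles(state)
  ux <- cos(mts$psi); uy <- sin(mts$psi)
  active <- mts$L > 0

  # chord geometry under bending
  factor <- rep(1, n)
  dirx <- ux; diry <- uy
  if (field$B > 0 && isTRUE(effects[["bending"]])) {
    theta <- mts$psi - field$direction_angle
    cl <- tip_deflection_um(mts$L, theta, field, consts)
    w <- cl$omega
    axial <- sqrt(pmax(mts$L^2 - w^2, 0))
    factor <- ifelse(active, axial / pmax(mts$L, .Machine$double.eps), 1)
    if (isTRUE(effects[["deviation"]])) {
      lat <- -sign(sin(2 * theta)) * w
      # chord direction from pole to deflected tip
      cx <- axial * ux + lat * (-uy)
      cy <- axial * uy + lat * ux
      cn <- sqrt(cx^2 + cy^2)
      ok <- active & cn > 0
      dirx[ok] <- cx[ok] / cn[ok]
      diry[ok] <- cy[ok] / cn[ok]
    }
    mts$clamped_bend <- cl$clamped & active
  }

  # length-proportional cytoplasmic pulling along the chord
  f_mag <- fp$alpha_cyto * mts$L * factor
  fx <- f_mag * dirx
  fy <- f_mag * diry

  # cortical forces at contacts: push antiparallel to growth direction,
  # dynein pull (chord-scaled) along it
  contact <- mts$at_cortex & active
  if (any(contact)) {
    bind <- contact & (u_bind < fp$p_bind)
    fx[contact] <- fx[contact] - fp$f_push * ux[contact]
    fy[contact] <- fy[contact] - fp$f_push * uy[contact]
    if (any(bind)) {
      fx[bind] <- fx[bind] + fp$f_dyn * factor[bind] * ux[bind]
      fy[bind] <- fy[bind] + fp$f_dyn * factor[bind] * uy[bind]
    }
  }

  rx <- poles[mts$pole_id, 1] - state$center[1]
  ry <- poles[mts$pole_id, 2] - state$center[2]
  torque <- sum(rx * fy - ry * fx)

  # rigid-rod magnetic torque transmitted to the spindle orientation
  if (field$B > 0 && isTRUE(effects[["rotation"]]) && any(active)) {
    theta <- mts$psi[active] - field$direction_angle
    tq_Nm <- -mt_torque(pmax(mts$L[active], .Machine$double.eps) * 1e-6,
                        theta, field, consts)
    torque <- torque + sum(tq_Nm) * 1e18   # N m -> pN um
  }

  list(force = c(sum(fx), sum(fy)), torque = torque)
}

#' Simulate spindle positioning and orientation
#'
#' Overdamped rigid-body dynamics: after each microtubule step the spindle
#' centre moves by `force / Gamma_t * dt` and its orientation by
#' `torque / Gamma_r * dt`, with the drags scaled from their 300-um
#' reference to the cell's semi-major axis (`a/300` translational,
#' `(a/300)^3` rotational): what moves is the spindle together with its
#' cell-spanning astral array, whose viscous drag grows with its extent.
#' This is what makes positioning slower in larger blastomeres. The run
#' is bit-reproducible for a fixed `cfg$seed`.
#'
#' @param init Initial [spindle_state()]; poles must lie inside `geom`.
#' @param geom A [cell_geometry()].
#' @param cfg A [sim_config()].
#' @param di [dynamic_instability_params()].
#' @param fp [force_params()].
#' @param consts [physical_constants()].
#' @return A `spindle_trajectory`: list with `t` (s), `d` (centre offset,
#'   um), `alpha` (rad) and `meta` (seed, field, geometry, config).
#' @examples
#' \donttest{
#' traj <- simulate_spindle(spindle_state(c(60, 30), 0.5),
#'                          cell_geometry(),
#'                          sim_config(t_max = 60, n_mt = 20, seed = 1))
#' utils::tail(traj$d, 1)
#' }
#' @export
simulate_spindle <- function(init, geom = cell_geometry(),
                             cfg = sim_config(),
                             di = dynamic_instability_params(),
                             fp = force_params(),
                             consts = physical_constants()) {
  p0 <- spindle_poles(init)
  if (!all(inside_ellipse(p0[, 1], p0[, 2], geom)))
    abort_invalid_geometry("initial spindle poles must lie inside the cell")
  set.seed(cfg$seed)

  # time acceleration of polymer turnover (see sim_config)
  di_eff <- dynamic_instability_params(v_g = di$v_g * cfg$speedup,
                                       v_s = di$v_s * cfg$speedup,
                                       f_cat = di$f_cat, f_res = di$f_res)
  field <- cfg$field
  gamma_t <- fp$Gamma_t * (geom$a / 300)
  gamma_r <- fp$Gamma_r * (geom$a / 300)^3
  n_steps <- ceiling(cfg$t_max / cfg$dt)
  n_rec <- length(seq(0, n_steps, by = cfg$stride))
  rec_t <- numeric(n_rec); rec_d <- numeric(n_rec); rec_a <- numeric(n_rec)

  center <- init$center
  alpha <- init$alpha
  s <- init$half_separation
  state <- spindle_state(center, alpha, s)
  mts <- nucleate_ensemble(state, cfg)
  n <- length(mts$L)

  k <- 1L
  rec_t[k] <- 0; rec_d[k] <- sqrt(sum(center^2)); rec_a[k] <- alpha
  for (i in seq_len(n_steps)) {
    draws <- list(u_switch = stats::runif(n))
    u_bind <- stats::runif(n)
    poles <- spindle_poles(state)
    mts <- step_microtubule(mts, poles, geom, di_eff, field, consts, cfg$dt,
                            effects = cfg$effects,
                            rotation_scale = cfg$speedup,
                            cortex_tol = cfg$cortex_tol, draws = draws)
    w <- net_wrench(state, mts, fp, field, consts,
                    effects = cfg$effects, u_bind = u_bind)
    center <- center + w$force / gamma_t * cfg$dt
    alpha <- alpha + w$torque / gamma_r * cfg$dt

    # keep the rigid spindle inside the cell (1 um margin)
    for (iter in 1:50) {
      pl <- rbind(center + s * c(cos(alpha), sin(alpha)),
                  center - s * c(cos(alpha), sin(alpha)))
      if (all(inside_ellipse(pl[, 1], pl[, 2], geom, margin = 1))) break
      center <- center * 0.98
    }
    if (!all(is.finite(center)) || sqrt(sum(center^2)) > geom$a)
      abort_instability(sprintf(
        "spindle centre left the cell at step %d; reduce dt (= %g s)", i, cfg$dt))
    state <- spindle_state(center, alpha, s)

    if (i %% cfg$stride == 0L) {
      k <- k + 1L
      rec_t[k] <- i * cfg$dt
      rec_d[k] <- sqrt(sum(center^2))
      rec_a[k] <- alpha
    }
  }
  structure(list(t = rec_t[1:k], d = rec_d[1:k], alpha = rec_a[1:k],
                 meta = list(seed = cfg$seed, field = field, geom = geom,
                             cfg = cfg)),
            class = "spindle_trajectory")
}

#' @export
print.spindle_trajectory <- function(x, ...) {
  cat(sprintf(
    "spindle_trajectory: %d samples over %g s (seed %d, B = %g T); final d = %.2f um, alpha = %.3f rad\n",
    length(x$t), max(x$t), x$meta$seed, x$meta$field$B,
    x$d[length(x$d)], x$alpha[length(x$alpha)]))
  invisible(x)
}
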