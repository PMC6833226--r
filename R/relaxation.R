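# Relaxation-time extraction from positioning/orientation trajectories and
# conversion of per-cycle slowdown into a whole-embryo delay over the early
# cleavage schedule.

series_from <- function(x, quantity = c("offset", "angle")) {
  quantity <- match.arg(quantity)
  if (inherits(x, "spindle_trajectory")) {
    y <- if (quantity == "offset") x$d else abs(axis_error(x$alpha))
    return(data.frame(t = x$t, y = y))
  }
  if (inherits(x, "trajectory_ensemble")) {
    m <- ensemble_mean(x)
    y <- if (quantity == "offset") m$d else m$abs_alpha
    return(data.frame(t = m$t, y = y))
  }
  if (is.data.frame(x)) {
    if (all(c("t", "y") %in% names(x))) return(x[, c("t", "y")])
    if (ncol(x) >= 2) return(stats::setNames(x[, 1:2], c("t", "y")))
  }
  abort_domain("cannot extract a (t, y) series from this object")
}

# Exponential fit y = y0 exp(-t / tau) by weighted least squares on log(y)
# (weights proportional to y, the standard variance stabilization for
# multiplicative noise). The fit window stops at the first crossing below
# 10% of the initial value, so the late-time fluctuation plateau of a
# stochastic trajectory does not bias tau.
fit_exponential_tau <- function(t, y) {
  y0 <- y[1]
  if (!is.finite(y0) || y0 <= 0)
    abort_no_relaxation("series must start positive to define a relaxation time")
  below <- which(y < 0.1 * y0)
  cut <- if (length(below)) min(below[below > 1], length(y)) else length(y)
  idx <- seq_len(max(cut, 3L))
  idx <- idx[idx <= length(y) & y[idx] > 0]
  if (length(idx) < 3L)
    abort_no_relaxation("too few positive points to fit a relaxation time")
  fit <- stats::lm(log(y[idx]) ~ t[idx], weights = y[idx])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    abort_no_relaxation("series does not decay; no relaxation time")
  # a fitted time far beyond the observation window means no measurable
  # decay (e.g. a constant series up to rounding)
  if (diff(range(t[idx])) < 0.05 * (-1 / slope))
    abort_no_relaxation("series shows no measurable decay over its window")
  list(tau = -1 / slope,
       fit_rms = sqrt(mean(stats::resid(fit)^2)),
       n_points = length(idx), method = "lsq")
}

# Fallback estimator: first crossing of y0/e, linearly interpolated.
efold_tau <- function(t, y) {
  y0 <- y[1]
  target <- y0 / exp(1)
  below <- which(y <= target)
  if (!length(below) || below[1] == 1L)
    abort_no_relaxation("series never decays to 1/e of its initial value")
  i <- below[1]
  frac <- (y[i - 1] - target) / (y[i - 1] - y[i])
  list(tau = t[i - 1] + frac * (t[i] - t[i - 1]),
       fit_rms = NA_real_, n_points = i, method = "efold")
}

#' Relaxation time of a decaying series
#'
#' Fits `y(t) = y0 exp(-t/tau)` to a positioning offset `d(t)` or
#' orientation error `|alpha(t)|` series (a single trajectory, an ensemble
#' mean, or any two-column data frame) by weighted least squares in the log
#' domain, falling back to the 1/e-crossing time if the fit degenerates.
#' Non-decaying series raise a `no_relaxation_error`.
#'
#' @param x A `spindle_trajectory`, `trajectory_ensemble`, or data frame
#'   with columns `t`, `y`.
#' @param quantity `"offset"` (centre offset) or `"angle"` (absolute
#'   orientation error to the long axis); ignored for plain data frames.
#' @return List with `tau` (time unit of `t`), `fit_rms` (log-domain RMS
#'   residual), `n_points`, and `method` (`"lsq"` or `"efold"`).
#' @examples
#' s <- make_decay_series(tau = 5, y0 = 60, noise_cv = 0, n_points = 100)
#' extract_relaxation_time(s)$tau   # 5
#' @export
extract_relaxation_time <- function(x, quantity = c("offset", "angle")) {
  s <- series_from(x, quantity)
  tryCatch(fit_exponential_tau(s$t, s$y),
           no_relaxation_error = function(e) stop(e),
           error = function(e) efold_tau(s$t, s$y))
}

#' Relaxation summary of a paired positioning/orientation ensemble
#'
#' @param ens A `trajectory_ensemble` (see [run_ensemble()]).
#' @return A `relaxation_summary`: `tau_d` and `tau_alpha` (s), their
#'   log-domain `fit_rms` values, and `n_runs`.
#' @export
relaxation_summary <- function(ens) {
  fd <- extract_relaxation_time(ens, "offset")
  fa <- extract_relaxation_time(ens, "angle")
  structure(list(tau_d = fd$tau, tau_alpha = fa$tau,
                 fit_rms = c(offset = fd$fit_rms, angle = fa$fit_rms),
                 n_runs = length(ens)),
            class = "relaxation_summary")
}

#' @export
print.relaxation_summary <- function(x, ...) {
  cat(sprintf("relaxation_summary: tau_d = %.3g s, tau_alpha = %.3g s (%d runs)\n",
              x$tau_d, x$tau_alpha, x$n_runs))
  invisible(x)
}

#' Normalize a trajectory's time axis
#'
#' Rescales time to the dimensionless `t* = t / tau_ref` (values are left
#' unchanged), the form in which positioning/orientation curves with and
#' without the field are compared.
#'
#' @param traj A `spindle_trajectory` or a data frame with a `t` column.
#' @param tau_ref Reference relaxation time (> 0), same unit as `t`.
#' @return The same object with `t` divided by `tau_ref`.
#' @export
normalize_trajectory <- function(traj, tau_ref) {
  stop_unless_number(tau_ref, "tau_ref", positive = TRUE)
  if (inherits(traj, "spindle_trajectory") ||
      (is.list(traj) && !is.data.frame(traj) && "t" %in% names(traj))) {
    traj$t <- traj$t / tau_ref
    return(traj)
  }
  if (is.data.frame(traj) && "t" %in% names(traj)) {
    traj$t <- traj$t / tau_ref
    return(traj)
  }
  abort_domain("`traj` must carry a `t` component")
}

#' Early cleavage schedule of the zebrafish embryo
#'
#' The first cleavage starts about 30-45 min after fertilization (default
#' midpoint 37.5 min); the embryo then divides synchronously every 15 min
#' for 8 further cycles. Cell linear dimensions shrink by `2^(-1/3)` per
#' cycle (volume halving) from the 600 x 300 um first-cleavage ellipse.
#'
#' @param first_cycle_min Duration of the first cycle, min.
#' @param n_synchronous_cycles Number of synchronous cycles after the first.
#' @param synchronous_cycle_min Duration of each synchronous cycle, min.
#' @param linear_scale_per_cycle Per-cycle linear scale factor of the cell.
#' @return A `cleavage_schedule` object.
#' @export
cleavage_schedule <- function(first_cycle_min = 37.5,
                              n_synchronous_cycles = 8,
                              synchronous_cycle_min = 15,
                              linear_scale_per_cycle = 2^(-1 / 3)) {
  stop_unless_number(first_cycle_min, "first_cycle_min", positive = TRUE)
  stop_unless_number(n_synchronous_cycles, "n_synchronous_cycles", nonneg = TRUE)
  stop_unless_number(synchronous_cycle_min, "synchronous_cycle_min", positive = TRUE)
  stop_unless_number(linear_scale_per_cycle, "linear_scale_per_cycle", positive = TRUE)
  structure(list(first_cycle_min = first_cycle_min,
                 n_synchronous_cycles = as.integer(n_synchronous_cycles),
                 synchronous_cycle_min = synchronous_cycle_min,
                 linear_scale_per_cycle = linear_scale_per_cycle),
            class = "cleavage_schedule")
}

#' Cycle durations of a cleavage schedule
#' @param schedule A [cleavage_schedule()].
#' @return Numeric vector of per-cycle durations, min.
#' @export
cycle_durations <- function(schedule) {
  c(schedule$first_cycle_min,
    rep(schedule$synchronous_cycle_min, schedule$n_synchronous_cycles))
}

#' Cell geometry at a given cleavage cycle
#' @param geom First-cleavage [cell_geometry()].
#' @param schedule A [cleavage_schedule()].
#' @param cycle Cycle index (1 = first cleavage).
#' @return The scaled `cell_geometry` for that cycle.
#' @export
geometry_for_cycle <- function(geom, schedule, cycle) {
  stop_unless_number(cycle, "cycle", positive = TRUE)
  scale_geometry(geom, schedule$linear_scale_per_cycle^(cycle - 1))
}

#' Accumulate per-cycle slowdown into a whole-embryo delay
#'
#' Each cycle whose positioning relaxation is slowed by a factor
#' `tau_ratio` needs `(tau_ratio - 1) * fraction * duration` extra minutes,
#' where `fraction` is the share of the cycle spent positioning/orienting
#' the spindle (default 1). The cumulative sum over the schedule is the
#' developmental delay estimate.
#'
#' @param tau_ratios Per-cycle relaxation-time ratios (field / control),
#'   non-negative; at most one per schedule cycle. Aligned with the first
#'   `length(tau_ratios)` cycles.
#' @param schedule A [cleavage_schedule()] or a plain numeric vector of
#'   cycle durations in minutes.
#' @param positioning_fraction Fraction of each cycle attributed to
#'   spindle positioning, in \[0, 1\].
#' @return A `delay_report`: `per_cycle_tau_ratio`, `per_cycle_extra_min`,
#'   `cumulative_delay_min`.
#' @examples
#' accumulate_delay(rep(1.2, 8), rep(15, 8))   # 24 min
#' @export
accumulate_delay <- function(tau_ratios, schedule = cleavage_schedule(),
                             positioning_fraction = 1) {
  if (any(!is.finite(tau_ratios)) || any(tau_ratios < 0))
    abort_domain("`tau_ratios` must be finite and non-negative")
  stop_unless_number(positioning_fraction, "positioning_fraction", nonneg = TRUE)
  if (positioning_fraction > 1)
    abort_domain("`positioning_fraction` must be in [0, 1]")
  durations <- if (inherits(schedule, "cleavage_schedule"))
    cycle_durations(schedule) else as.numeric(schedule)
  if (length(tau_ratios) > length(durations))
    abort_domain("more `tau_ratios` than schedule cycles")
  extra <- (tau_ratios - 1) * positioning_fraction *
    durations[seq_along(tau_ratios)]
  structure(list(per_cycle_tau_ratio = tau_ratios,
                 per_cycle_extra_min = extra,
                 cumulative_delay_min = sum(extra)),
            class = "delay_report")
}

#' @export
print.delay_report <- function(x, ...) {
  cat(sprintf("delay_report: %d cycles, cumulative delay %.2f min\n",
              length(x$per_cycle_extra_min), x$cumulative_delay_min))
  invisible(x)
}
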