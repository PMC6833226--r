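# Synthetic fixtures: every input the pipeline needs, generated in code
# with the statistical structure the simulator assumes. One global seed
# fans out to per-component streams through child_seed(), so adding
# fixtures never perturbs existing ones.

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting rule `(seed * 48271 + i * 1299721) mod
#' (2^31 - 1)`: a fixed parent seed and index always give the same child,
#' and distinct indices give distinct streams.
#'
#' @param seed Parent integer seed.
#' @param i Child index (vectorized).
#' @return Integer child seed(s) in \[1, 2^31 - 1\].
#' @export
child_seed <- function(seed, i) {
  s <- (as.double(seed) * 48271 + as.double(i) * 1299721) %% 2147483647
  as.integer(s + 1)
}

#' Synthetic noisy exponential decay series
#'
#' Ground truth for relaxation-time recovery:
#' `y(t) = y0 exp(-t/tau) (1 + eps)` with `eps` i.i.d. mean-zero Gaussian
#' of standard deviation `noise_cv`.
#'
#' @param tau True relaxation time (> 0), s.
#' @param y0 Initial value.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_points Number of samples on \[0, t_max\].
#' @param seed Integer seed.
#' @param t_max Series duration; default `5 * tau`.
#' @return Data frame with columns `t`, `y`.
#' @export
make_decay_series <- function(tau, y0 = 60, noise_cv = 0, n_points = 200,
                              seed = 1L, t_max = 5 * tau) {
  stop_unless_number(tau, "tau", positive = TRUE)
  stop_unless_number(noise_cv, "noise_cv", nonneg = TRUE)
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  eps <- if (noise_cv > 0) stats::rnorm(n_points, 0, noise_cv) else 0
  data.frame(t = t, y = y0 * exp(-t / tau) * (1 + eps))
}

#' Randomized initial spindle states inside a cell
#'
#' Initial centres uniform in the concentric half-scale ellipse (rejection
#' sampling), orientation uniform on \[-pi/2, pi/2); every generated state
#' has both poles inside the cell.
#'
#' @param geom A [cell_geometry()].
#' @param n Number of states (>= 1).
#' @param seed Integer seed.
#' @param half_separation Spindle pole half-distance, um.
#' @return List of [spindle_state()] objects.
#' @export
make_init_condition_sweep <- function(geom = cell_geometry(), n = 1,
                                      seed = 1L, half_separation = 30) {
  if (n < 1) abort_domain("`n` must be >= 1")
  set.seed(seed)
  half <- scale_geometry(geom, 0.5)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    repeat {
      cx <- stats::runif(1, -half$a, half$a)
      cy <- stats::runif(1, -half$b, half$b)
      if (!inside_ellipse(cx, cy, half)) next
      alpha <- stats::runif(1, -pi / 2, pi / 2)
      st <- tryCatch(spindle_state(c(cx, cy), alpha, half_separation, geom),
                     invalid_geometry_error = function(e) NULL)
      if (!is.null(st)) break
    }
    out[[k]] <- st
  }
  out
}

#' Paired field/control simulation configurations
#'
#' Builds `cfg$ensemble_n` pairs of configurations identical in every
#' field except the magnetic flux density, with pair i of both lists
#' sharing the seed `child_seed(cfg$seed, i)` (common random numbers for
#' variance reduction in paired comparisons).
#'
#' @param cfg A [sim_config()] template.
#' @param B_values Field strengths of the two conditions, T (default
#'   control 0 and exposure 9).
#' @return Named list of two lists of `sim_config`, one per field value.
#' @export
make_paired_field_ensemble <- function(cfg, B_values = c(0, 9)) {
  if (length(B_values) != 2L || any(B_values < 0))
    abort_invalid_field("`B_values` must be two non-negative field strengths")
  seeds <- child_seed(cfg$seed, seq_len(cfg$ensemble_n))
  build <- function(B) {
    lapply(seeds, function(s) {
      ci <- cfg
      ci$seed <- as.integer(s)
      ci$field <- field_spec(B, cfg$field$direction_angle)
      ci
    })
  }
  stats::setNames(lapply(B_values, build), sprintf("B%g", B_values))
}
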