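# Shared helpers for the test suite.

# Independent oracle: the magnetic torque/energy amplitude Delta_chi B^2 /
# (2 mu0), evaluated straight from the printed constants (not through the
# package).
oracle_amplitude <- function(B = 9, delta_chi = 1.243e-32, mu0 = 4e-7 * pi) {
  delta_chi * B^2 / (2 * mu0)
}

# Independent oracle: deflection by nested numerical double quadrature of
# the distributed bending moment divided by EI, with clamped boundary
# (omega(0) = omega'(0) = 0).
oracle_deflection <- function(x, L, theta, B = 9,
                              consts = physical_constants()) {
  Mfun <- function(u)
    (13 * consts$delta_chi * B^2 / (2 * consts$d0 * consts$mu0)) *
      (L - u) * sin(2 * theta) / consts$EI
  slope <- function(s)
    stats::integrate(Mfun, 0, s, rel.tol = 1e-11)$value
  vapply(x, function(xx)
    stats::integrate(Vectorize(slope), 0, xx, rel.tol = 1e-10)$value,
    numeric(1))
}

# Small controlled microtubule ensemble for wrench tests.
make_mts <- function(pole_id, psi, L,
                     growing = rep(TRUE, length(L)),
                     at_cortex = rep(FALSE, length(L))) {
  spindlemag:::mt_ensemble(pole_id, psi, L, growing, at_cortex,
                           rep(FALSE, length(L)))
}

# Standard first-cleavage setup used by the behavioural tests: a displaced,
# misoriented spindle in the 600 x 300 um cell.
std_init <- function(scale = 1) spindle_state(c(60, 30) * scale, 0.5)

# Cached heavy ensembles shared across acceptance blocks (computed once
# per test run).
.acc_cache <- new.env(parent = emptyenv())
acc_cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) assign(key, expr, envir = .acc_cache)
  get(key, envir = .acc_cache)
}

acc_cfg <- function(...) {
  args <- utils::modifyList(
    list(t_max = 1500, n_mt = 50, seed = 1, ensemble_n = 20), list(...))
  do.call(sim_config, args)
}
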