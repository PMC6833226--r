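# Monte Carlo spindle simulator: nucleation, microtubule stepping, force
# summation and the overdamped spindle update.

test_that("nucleation gives the requested count with isotropic directions", {
  st <- spindle_state()
  set.seed(1)
  mts <- nucleate_ensemble(st, sim_config(n_mt = 1))
  expect_length(mts$L, 2L)
  expect_true(all(mts$L == 0) && all(mts$growing))

  set.seed(2)
  big <- nucleate_ensemble(st, sim_config(n_mt = 5000))
  # angular mean resultant length of the 10^4 directions
  R <- sqrt(mean(cos(big$psi))^2 + mean(sin(big$psi))^2)
  expect_lt(R, 0.05)
  # marginal spread covers the circle
  expect_gt(min(big$psi), -1e-9)
  expect_lt(max(big$psi), 2 * pi)

  set.seed(7); a <- nucleate_ensemble(st, sim_config(n_mt = 40))
  set.seed(7); b <- nucleate_ensemble(st, sim_config(n_mt = 40))
  expect_identical(a, b)
})

test_that("microtubule stepping is exact for deterministic growth", {
  geom <- cell_geometry()
  poles <- spindle_poles(spindle_state())
  cst <- physical_constants()
  di <- dynamic_instability_params(v_g = 0.125, f_cat = 0, f_res = 0)
  mts <- make_mts(c(1L, 2L), c(0.3, 4.0), c(10, 20))

  out <- step_microtubule(mts, poles, geom, di, field_spec(0), cst, dt = 1)
  expect_equal(out$L, c(10, 20) + 0.125, tolerance = 1e-15)
  expect_identical(out$growing, c(TRUE, TRUE))
  expect_identical(out$psi, mts$psi)   # no field, no rotation

  # shrinkage and template renucleation from zero length
  mts2 <- make_mts(1L, 1.2, 0.1, growing = FALSE)
  out2 <- step_microtubule(mts2, poles, geom, di, field_spec(0), cst, dt = 1)
  expect_identical(out2$L, 0)
  expect_true(out2$growing)
  expect_identical(out2$psi, 1.2)
})

test_that("field-modulated growth follows the direction-dependent rate", {
  geom <- cell_geometry()
  poles <- spindle_poles(spindle_state())
  cst <- physical_constants()
  f9 <- field_spec(9, direction_angle = pi / 2)
  di <- dynamic_instability_params(v_g = 0.125, f_cat = 0, f_res = 0)
  # psi = pi is perpendicular to a field along the short axis
  mts <- make_mts(1L, pi, 50)
  out <- step_microtubule(mts, poles, geom, di, f9, cst, dt = 1)
  expected <- 0.125 * exp(-oracle_amplitude(9) / (cst$kB * cst$T_abs))
  expect_equal(out$L - 50, expected, tolerance = 1e-12)
  # parallel growth is unaffected
  mts_par <- make_mts(1L, pi / 2, 50)
  out_par <- step_microtubule(mts_par, poles, geom, di, f9, cst, dt = 1)
  expect_equal(out_par$L - 50, 0.125, tolerance = 1e-15)
})

test_that("tips are truncated at the cortex and flagged", {
  geom <- cell_geometry()
  st <- spindle_state()
  poles <- spindle_poles(st)
  cst <- physical_constants()
  di <- dynamic_instability_params(v_g = 1000, f_cat = 0, f_res = 0)
  mts <- make_mts(1L, 0, 10)
  out <- step_microtubule(mts, poles, geom, di, field_spec(0), cst, dt = 1)
  reach <- spindlemag:::ray_to_boundary(poles[1, 1], poles[1, 2], 0, geom)
  expect_equal(out$L, reach, tolerance = 1e-12)
  expect_true(out$at_cortex)
})

test_that("oversized switching probabilities are rejected", {
  geom <- cell_geometry()
  poles <- spindle_poles(spindle_state())
  di <- dynamic_instability_params(f_cat = 3, f_res = 0)
  expect_error(
    step_microtubule(make_mts(1L, 0, 10), poles, geom, di, field_spec(0),
                     physical_constants(), dt = 1),
    class = "timestep_too_large_error")
})

test_that("net wrench vanishes for empty and mirror-symmetric ensembles", {
  st <- spindle_state()
  fp <- force_params()
  empty <- make_mts(integer(0), numeric(0), numeric(0))
  w0 <- net_wrench(st, empty, fp)
  expect_identical(w0$force, c(0, 0))
  expect_identical(w0$torque, 0)

  # fourfold-symmetric fans at both poles, away from the cortex
  psi <- rep(c(pi / 4, 3 * pi / 4, 5 * pi / 4, 7 * pi / 4), 2)
  mts <- make_mts(rep(1:2, each = 4), psi, rep(40, 8))
  w <- net_wrench(st, mts, fp, u_bind = rep(1, 8))
  expect_lt(max(abs(c(w$force, w$torque))), 1e-12)
})

test_that("a single free microtubule pulls with alpha_cyto times its length", {
  st <- spindle_state()
  fp <- force_params()
  mts <- make_mts(1L, 0.7, 80)
  w <- net_wrench(st, mts, fp, u_bind = 1)
  expect_equal(sqrt(sum(w$force^2)), fp$alpha_cyto * 80, tolerance = 1e-12)
  expect_equal(atan2(w$force[2], w$force[1]), 0.7, tolerance = 1e-12)
})

test_that("cortical contacts add push and, on binding, dynein pull", {
  st <- spindle_state()
  fp <- force_params()
  mts <- make_mts(1L, 0, 100, at_cortex = TRUE)
  # no binding
  w_push <- net_wrench(st, mts, fp, u_bind = 1)
  expect_equal(w_push$force[1], fp$alpha_cyto * 100 - fp$f_push,
               tolerance = 1e-12)
  # guaranteed binding
  w_bind <- net_wrench(st, mts, fp, u_bind = 0)
  expect_equal(w_bind$force[1],
               fp$alpha_cyto * 100 - fp$f_push + fp$f_dyn, tolerance = 1e-12)
})

test_that("bending scales pulling by the chord factor when the field is on", {
  st <- spindle_state()
  fp <- force_params(f_push = 0, f_dyn = 0)
  cst <- physical_constants()
  f9 <- field_spec(9, direction_angle = pi / 2)
  L <- 200
  mts <- make_mts(1L, pi / 4, L)    # 45 deg to the field: maximal bending
  w <- net_wrench(st, mts, fp, f9, cst,
                  effects = c(bending = TRUE, rotation = FALSE,
                              deviation = FALSE),
                  u_bind = 1)
  theta <- pi / 4 - pi / 2
  K <- 13 * cst$delta_chi * 81 / (2 * cst$d0 * cst$mu0 * cst$EI)
  w_um <- min(abs(K * sin(2 * theta)) * (L * 1e-6)^3 / 3 * 1e6, 0.99 * L)
  expected <- fp$alpha_cyto * L * sqrt(L^2 - w_um^2) / L
  expect_equal(sqrt(sum(w$force^2)), expected, tolerance = 1e-12)
  expect_lt(sqrt(sum(w$force^2)), fp$alpha_cyto * L)
})

test_that("simulation is bit-reproducible and records a valid trajectory", {
  cfg <- sim_config(t_max = 30, n_mt = 10, seed = 5)
  a <- simulate_spindle(std_init(), cell_geometry(), cfg)
  b <- simulate_spindle(std_init(), cell_geometry(), cfg)
  expect_identical(a[c("t", "d", "alpha")], b[c("t", "d", "alpha")])
  expect_true(all(diff(a$t) > 0))
  expect_true(all(a$d >= 0))
  expect_equal(a$d[1], sqrt(60^2 + 30^2), tolerance = 1e-12)

  cfg2 <- sim_config(t_max = 30, n_mt = 10, seed = 6)
  c2 <- simulate_spindle(std_init(), cell_geometry(), cfg2)
  expect_false(identical(a$d, c2$d))
  expect_error(
    simulate_spindle(spindle_state(c(280, 0), 0), cell_geometry(),
                     sim_config(t_max = 10, n_mt = 5)),
    class = "invalid_geometry_error")
})

test_that("paired field runs consume identical random streams", {
  cfg0 <- sim_config(t_max = 40, n_mt = 10, seed = 9, field = field_spec(0))
  cfg9 <- sim_config(t_max = 40, n_mt = 10, seed = 9, field = field_spec(9))
  a <- simulate_spindle(std_init(), cell_geometry(), cfg0)
  b <- simulate_spindle(std_init(), cell_geometry(), cfg9)
  # common random numbers: early trajectories track each other closely
  expect_lt(max(abs(a$d - b$d)) / a$d[1], 0.05)
})
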