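# Closed-form magneto-physics: frozen oracle values, consistency between
# torque and energy, and the beam-deflection solution.

test_that("dimer torque follows the sin(2 theta) law with the printed amplitude", {
  f9 <- field_spec(9)
  amp <- oracle_amplitude(9)                      # 4.006049e-25 N m
  expect_identical(dimer_torque(0, f9), 0)
  expect_identical(dimer_torque(pi / 2, f9), amp * sin(pi))  # sin(pi) underflow-free
  expect_equal(dimer_torque(pi / 4, f9), amp, tolerance = 1e-12)
  expect_equal(dimer_torque(pi / 4, f9), 4.006049e-25, tolerance = 1e-6)
  # period pi
  th <- seq(-3, 3, length.out = 41)
  expect_equal(dimer_torque(th + pi, f9), dimer_torque(th, f9),
               tolerance = 1e-12)
  expect_error(field_spec(-1), class = "invalid_field_error")
})

test_that("orientation energy is the integral of the torque", {
  f9 <- field_spec(9)
  amp <- oracle_amplitude(9)
  expect_identical(dimer_orientation_energy(0, f9), 0)
  expect_equal(dimer_orientation_energy(pi / 2, f9), amp, tolerance = 1e-12)
  # dE/dtheta = torque, central differences, 100 random angles
  set.seed(1)
  th <- stats::runif(100, -pi, pi)
  h <- 1e-6
  dE <- (dimer_orientation_energy(th + h, f9) -
           dimer_orientation_energy(th - h, f9)) / (2 * h)
  tq <- dimer_torque(th, f9)
  expect_lt(max(abs(dE - tq)) / max(abs(tq)), 1e-6)
})

test_that("Boltzmann orientation density normalizes and matches the energy ratio", {
  f9 <- field_spec(9)
  cst <- physical_constants()
  # uniform at zero field
  expect_equal(dimer_orientation_pdf(c(-1, 0, 1), field_spec(0)),
               rep(1 / pi, 3), tolerance = 1e-12)
  # normalization on the planar support
  Z <- stats::integrate(function(th) dimer_orientation_pdf(th, f9),
                        -pi / 2, pi / 2, rel.tol = 1e-12)$value
  expect_equal(Z, 1, tolerance = 1e-8)
  # density ratio perpendicular/parallel cancels the normalization
  ratio <- dimer_orientation_pdf(pi / 2 - 1e-12, f9) /
    dimer_orientation_pdf(0, f9)
  expect_equal(ratio, exp(-oracle_amplitude(9) / (cst$kB * cst$T_abs)),
               tolerance = 1e-9)
  # spherical option also normalizes
  Zs <- stats::integrate(function(th)
    dimer_orientation_pdf(th, f9, support = "spherical"),
    0, pi, rel.tol = 1e-12)$value
  expect_equal(Zs, 1, tolerance = 1e-8)
})

test_that("polymerization rate is v0 parallel to the field and slowest perpendicular", {
  f9 <- field_spec(9)
  cst <- physical_constants()
  expect_identical(polymerization_rate(0, f9), cst$v0)
  expect_identical(polymerization_rate(0, f9), 1.25e-7)
  expect_identical(polymerization_rate(0.7, field_spec(0)), cst$v0)
  expect_equal(polymerization_rate(pi / 2, f9),
               1.25e-7 * exp(-oracle_amplitude(9) / (cst$kB * cst$T_abs)),
               tolerance = 1e-12)
  # strictly decreasing on [0, pi/2], symmetric about pi/2
  th <- seq(0, pi / 2, length.out = 50)
  expect_true(all(diff(polymerization_rate(th, f9)) < 0))
  expect_equal(polymerization_rate(th, f9), polymerization_rate(pi - th, f9),
               tolerance = 1e-15)
})

test_that("whole-microtubule torque scales with the dimer count 13 L / d0", {
  f9 <- field_spec(9)
  L <- 1e-4                                        # 100 um
  expected <- (13 * L / 8e-9) * oracle_amplitude(9)
  expect_equal(mt_torque(L, pi / 4, f9), expected, tolerance = 1e-12)
  expect_equal(mt_torque(L, pi / 4, f9), 6.51e-20, tolerance = 1e-3)
  expect_equal(mt_torque(2 * L, 0.3, f9), 2 * mt_torque(L, 0.3, f9),
               tolerance = 1e-15)
  expect_identical(mt_torque(L, 0, f9), 0)
  expect_error(mt_torque(-1e-6, 0.3, f9), class = "invalid_geometry_error")
})

test_that("rotation rate peaks at 45 degrees and matches the drag balance", {
  f9 <- field_spec(9)
  L <- 1e-4
  expect_equal(mt_rotation_rate(L, pi / 4, f9),
               2 * (13 * L / 8e-9) * oracle_amplitude(9) / (1e-3 * L^2),
               tolerance = 1e-12)
  expect_equal(mt_rotation_rate(L, pi / 4, f9), 1.302e-8, tolerance = 1e-3)
  expect_identical(mt_rotation_rate(L, 0, f9), 0)
  peak <- stats::optimize(function(th) mt_rotation_rate(L, th, f9),
                          c(0, pi / 2), maximum = TRUE, tol = 1e-10)
  expect_equal(peak$maximum, pi / 4, tolerance = 1e-6)
})

test_that("bending moment is linear in distance from the free end", {
  f9 <- field_spec(9)
  L <- 2e-4
  m0 <- bending_moment(0, L, pi / 4, f9)
  expect_equal(m0, (13 * 1.243e-32 * 81 / (2 * 8e-9 * 4e-7 * pi)) * L,
               tolerance = 1e-12)
  expect_identical(bending_moment(L, L, pi / 4, f9), 0)
  expect_equal(bending_moment(L / 2, L, pi / 4, f9), m0 / 2,
               tolerance = 1e-12)
  expect_error(bending_moment(-1e-6, L, 0.3, f9), class = "domain_error")
  expect_error(bending_moment(2 * L, L, 0.3, f9), class = "domain_error")
})

test_that("deflection matches the independent double quadrature and scaling laws", {
  f9 <- field_spec(9)
  prof <- deflection(50e-6, pi / 4, f9)
  expect_equal(prof$omega_max * 1e6, 0.819, tolerance = 1e-3)
  expect_equal(prof$omega_max,
               oracle_deflection(50e-6, 50e-6, pi / 4), tolerance = 1e-8)
  expect_identical(unname(prof$deflection[1]), 0)
  expect_equal(prof$omega_max, prof$deflection[length(prof$deflection)],
               tolerance = 1e-15)
  # exact cubic/quadratic scaling in L and B
  w1 <- deflection(40e-6, 0.5, f9)$omega_max
  w2 <- deflection(80e-6, 0.5, f9)$omega_max
  expect_equal(log(w2 / w1) / log(2), 3, tolerance = 1e-9)
  w3 <- deflection(40e-6, 0.5, field_spec(4.5))$omega_max
  expect_equal(log(w1 / w3) / log(2), 2, tolerance = 1e-9)
  # B = 0 is exactly straight
  expect_true(all(deflection(1e-4, 0.7, field_spec(0))$deflection == 0))
  # CSV-facing frame
  df <- as.data.frame(prof)
  expect_named(df, c("x_m", "moment_Nm", "deflection_m"))
})

test_that("effective pulling force is the chord projection", {
  expect_identical(effective_pulling_force(1.5, 50, 0), 1.5)
  expect_equal(effective_pulling_force(1, 50, 30), 0.8, tolerance = 1e-12)
  # monotone non-increasing in the deflection, vanishing limit
  w <- seq(0, 49.99, length.out = 200)
  f <- effective_pulling_force(1, 50, w)
  expect_true(all(diff(f) <= 0))
  expect_lt(effective_pulling_force(1, 50, 50 - 1e-9), 1e-4)
  expect_error(effective_pulling_force(1, 50, 50),
               class = "degenerate_bending_error")
  clamped <- clamp_deflection(c(10, 80), 50)
  expect_equal(clamped$omega, c(10, 49.5))
  expect_identical(clamped$clamped, c(FALSE, TRUE))
})

test_that("zero field nullifies every magnetic quantity exactly", {
  f0 <- field_spec(0)
  th <- seq(-pi, pi, length.out = 21)
  expect_true(all(dimer_torque(th, f0) == 0))
  expect_true(all(dimer_orientation_energy(th, f0) == 0))
  expect_true(all(mt_torque(1e-4, th, f0) == 0))
  expect_true(all(mt_rotation_rate(1e-4, th, f0) == 0))
  expect_true(all(bending_moment(c(0, 5e-5), 1e-4, 0.4, f0) == 0))
  expect_identical(polymerization_rate(th, f0), rep(1.25e-7, length(th)))
})
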