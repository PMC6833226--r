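# Relaxation-time extraction and cleavage-delay accumulation.

test_that("the exact exponential is recovered to machine-level accuracy", {
  s <- make_decay_series(tau = 5, y0 = 60, noise_cv = 0, n_points = 200)
  fit <- extract_relaxation_time(s)
  expect_equal(fit$tau, 5, tolerance = 1e-6)
  expect_lt(fit$fit_rms, 1e-10)
  expect_identical(fit$method, "lsq")
})

test_that("noisy exponentials are recovered within a few percent", {
  s <- make_decay_series(tau = 5, y0 = 60, noise_cv = 0.01, n_points = 200,
                         seed = 4)
  fit <- extract_relaxation_time(s)
  expect_lt(abs(fit$tau - 5) / 5, 0.05)
})

test_that("non-decaying series raise a no-relaxation error", {
  flat <- data.frame(t = 0:50, y = rep(3, 51))
  expect_error(extract_relaxation_time(flat), class = "no_relaxation_error")
  rising <- data.frame(t = 0:50, y = exp((0:50) / 30))
  expect_error(extract_relaxation_time(rising), class = "no_relaxation_error")
  expect_error(extract_relaxation_time(data.frame(t = 0:10, y = rep(0, 11))),
               class = "no_relaxation_error")
})

test_that("the estimator is scale-equivariant in time", {
  s <- make_decay_series(tau = 7, y0 = 10, noise_cv = 0.02, n_points = 150,
                         seed = 11)
  tau1 <- extract_relaxation_time(s)$tau
  s2 <- s; s2$t <- s2$t * 3.5
  tau2 <- extract_relaxation_time(s2)$tau
  expect_equal(tau2, 3.5 * tau1, tolerance = 1e-9)
})

test_that("normalization divides the time axis and nothing else", {
  s <- make_decay_series(tau = 4, y0 = 20, noise_cv = 0, n_points = 50)
  n1 <- normalize_trajectory(s, 1)
  expect_equal(n1, s)
  n2 <- normalize_trajectory(s, 2)
  expect_equal(n2$t, s$t / 2)
  expect_identical(n2$y, s$y)
  # a clean decay normalized by its own tau crosses 1/e at t* = 1
  fit <- extract_relaxation_time(s)
  ns <- normalize_trajectory(s, fit$tau)
  i <- which(ns$y <= 20 / exp(1))[1]
  expect_equal(ns$t[i], 1, tolerance = 0.15)
  expect_error(normalize_trajectory(s, -1), class = "domain_error")
})

test_that("the cleavage schedule carries the early-embryo defaults", {
  sch <- cleavage_schedule()
  expect_equal(cycle_durations(sch), c(37.5, rep(15, 8)))
  g1 <- geometry_for_cycle(cell_geometry(), sch, 1)
  expect_equal(c(g1$a, g1$b), c(300, 150))
  g4 <- geometry_for_cycle(cell_geometry(), sch, 4)
  expect_equal(g4$a, 300 * 2^(-1), tolerance = 1e-12)  # three halvings of volume
})

test_that("delay accumulation reproduces hand-computed totals", {
  expect_equal(accumulate_delay(rep(1.2, 8), rep(15, 8))$cumulative_delay_min,
               24, tolerance = 1e-12)
  expect_equal(accumulate_delay(2, 15)$cumulative_delay_min, 15)
  r <- accumulate_delay(rep(1, 9), cleavage_schedule())
  expect_identical(r$cumulative_delay_min, 0)
  # positioning fraction scales linearly
  half <- accumulate_delay(rep(1.2, 8), rep(15, 8), positioning_fraction = 0.5)
  expect_equal(half$cumulative_delay_min, 12, tolerance = 1e-12)
  expect_error(accumulate_delay(-0.2, rep(15, 8)), class = "domain_error")
  expect_error(accumulate_delay(rep(1.1, 10), cleavage_schedule()),
               class = "domain_error")
})

test_that("delay accumulation is additive over schedule concatenation", {
  r_all <- accumulate_delay(c(1.3, 1.1, 1.2), c(30, 15, 15))
  r_a <- accumulate_delay(1.3, 30)
  r_b <- accumulate_delay(c(1.1, 1.2), c(15, 15))
  expect_equal(r_all$cumulative_delay_min,
               r_a$cumulative_delay_min + r_b$cumulative_delay_min,
               tolerance = 1e-12)
})
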