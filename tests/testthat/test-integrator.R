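test_that("simulation config enforces the whole-step rule", {
  cfg <- fr_config()
  expect_equal(cfg$t_max, 1)
  expect_equal(cfg$dt, 1 / 1024)
  expect_equal(cfg$n_steps, 1024L)
  expect_error(fr_config(t_max = 1, dt = 0.3), "integer multiple")
  expect_error(fr_config(t_max = 1, dt = 2), "dt")
  expect_error(fr_config(t_max = -1), "t_max")
})

test_that("no-learning limit reproduces the Holling disk equation", {
  p <- fr_predator(a0 = 0.1, am = 0.1, h0 = 0.1, hm = 0.1)
  tr <- simulate_fixed_density(p, 100, fr_config())
  expect_equal(final_consumed(tr), 5, tolerance = 1e-12)  # constant RHS
  for (D in c(1, 7.5, 50, 200)) {
    got <- final_consumed(simulate_fixed_density(p, D, fr_config()))
    want <- holling_closed_form(0.1, 0.1, D, 1)
    expect_lt(abs(got - want) / want, 1e-9)
  }
  expect_equal(final_consumed(simulate_fixed_density(p, 0, fr_config())), 0)
})

test_that("separable attack-learning case matches its analytic solution", {
  # dN/dt = 10 (1 - 0.5 e^{-N}) separates to N(T) = log(0.5 (1 + e^10))
  p <- fr_predator(a0 = 0.5, am = 1, la = 1, h0 = 0, hm = 0, lh = 0)
  got <- final_consumed(simulate_fixed_density(p, 10, fr_config()))
  expect_lt(abs(got - log(0.5 * (1 + exp(10)))), 1e-6)
})

test_that("no-learning depletion matches the Rogers implicit solution", {
  p <- fr_predator(a0 = 0.1, am = 0.1, h0 = 0.1, hm = 0.1)
  cfg <- fr_config(depletion = TRUE)
  for (N0 in c(5, 50, 100, 200)) {
    got <- final_consumed(simulate_depletion(p, N0, cfg))
    expect_lt(abs(got - rogers_closed_form(0.1, 0.1, N0, 1)), 1e-7)
  }
  ph0 <- fr_predator(a0 = 0.1, am = 0.1, h0 = 0, hm = 0)
  got <- final_consumed(simulate_depletion(ph0, 100, cfg))
  expect_lt(abs(got - 100 * (1 - exp(-0.1))), 1e-7)
  expect_equal(final_consumed(simulate_depletion(p, 0, cfg)), 0)
})

test_that("trajectories respect the state-variable invariants", {
  p <- fr_predator(a0 = 0.1, am = 1, la = 0.8, h0 = 0.5, hm = 0.05,
                   lh = 0.6)
  tr <- simulate_fixed_density(p, 80, fr_config())
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(diff(tr$n_consumed) >= 0))
  expect_true(all(diff(tr$a) >= 0))
  expect_true(all(diff(tr$h) <= 0))
  trd <- simulate_depletion(p, 80, fr_config(depletion = TRUE))
  expect_true(all(trd$n_consumed >= 0 & trd$n_consumed <= 80))
  expect_true(all(diff(trd$n_available) <= 1e-12))
  expect_equal(trd$n_available, 80 - trd$n_consumed)
})

test_that("closed-form substitution agrees with the coupled-system formulation", {
  cfg_h <- fr_config()
  cfg_r <- fr_config(depletion = TRUE)
  for (p in draw_predators(6, seed = 11L)) {
    a <- final_consumed(simulate_fixed_density(p, 60, cfg_h))
    b <- final_consumed(simulate_fixed_density(p, 60, cfg_h, "coupled"))
    expect_lt(abs(a - b), 1e-6)
    a <- final_consumed(simulate_depletion(p, 60, cfg_r))
    b <- final_consumed(simulate_depletion(p, 60, cfg_r, "coupled"))
    expect_lt(abs(a - b), 1e-6)
  }
})

test_that("integrator shows fourth-order global convergence", {
  p <- fr_predator(a0 = 0.1, am = 1, la = 1, h0 = 1, hm = 0.05, lh = 1)
  final_at <- function(dt)
    final_consumed(simulate_fixed_density(p, 50, fr_config(dt = dt)))
  n16 <- final_at(1 / 16); n32 <- final_at(1 / 32)
  n64 <- final_at(1 / 64); n128 <- final_at(1 / 128)
  r1 <- (n16 - n32) / (n32 - n64)
  r2 <- (n32 - n64) / (n64 - n128)
  expect_gt(r1, 10); expect_lt(r1, 24)   # ~2^4 = 16
  expect_gt(r2, 10); expect_lt(r2, 24)
})

test_that("compiled curve kernel matches the deSolve route exactly", {
  offered <- seq(2, 30, by = 4)
  for (depl in c(FALSE, TRUE)) {
    cfg <- fr_config(depletion = depl)
    p <- fr_predator(a0 = 0.15, am = 1, la = 0.4, h0 = 0.8, hm = 0.05,
                     lh = 0.3)
    a <- response_curve(p, offered, cfg, engine = "compiled")
    b <- response_curve(p, offered, cfg, engine = "desolve")
    expect_equal(a$consumed, b$consumed, tolerance = 1e-12)
  }
})

test_that("response curves validate their grid and setting", {
  p <- fr_predator(a0 = 0.1, am = 0.1, h0 = 0.1, hm = 0.1)
  expect_error(response_curve(p, c(1, 2, 3), fr_config()), "length >= 7")
  expect_error(response_curve(p, c(1, 2, 4, 5, 6, 7, 8), fr_config()),
               "uniformly spaced")
  expect_error(response_curve(p, rev(seq(1, 10)), fr_config()),
               "increasing")
  expect_error(simulate_fixed_density(p, 10, fr_config(depletion = TRUE)),
               "depletion = FALSE")
  expect_error(simulate_depletion(p, 10, fr_config()), "depletion = TRUE")
  # no-learning curve equals the disk equation pointwise
  offered <- seq(1, 200, by = 1)
  rc <- response_curve(p, offered, fr_config())
  expect_true(all(abs(rc$consumed -
                        holling_closed_form(0.1, 0.1, offered, 1)) < 1e-9))
  expect_true(all(diff(rc$consumed) >= 0))
})
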