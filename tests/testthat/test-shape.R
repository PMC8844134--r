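test_that("central differences are exact on low-order polynomials", {
  x <- seq(0, 10, by = 0.5)
  lin <- finite_differences(fr_curve(x, 2 * x + 1))
  expect_true(all(abs(lin$d2) < 1e-10))
  expect_true(all(abs(lin$d1 - 2) < 1e-10))
  quad <- finite_differences(fr_curve(x, x^2))
  expect_true(all(abs(quad$d2 - 2) < 1e-9))
  cub <- finite_differences(fr_curve(seq(0, 6), seq(0, 6)^3))
  expect_equal(cub$d2[cub$offered == 2], 12, tolerance = 1e-12)
})

test_that("normalized second derivative is the affinely rescaled one", {
  x <- seq(1, 21, by = 1)
  y <- 3 + 0.4 * x^2
  pr <- finite_differences(fr_curve(x, y))
  rx <- diff(range(x)); ry <- diff(range(y))
  expect_equal(pr$normalized_d2, pr$d2 * rx^2 / ry, tolerance = 1e-12)
  # constant curve: zero range handled as identically-zero rescaling
  flat <- finite_differences(fr_curve(x, rep(2, length(x))))
  expect_true(all(flat$normalized_d2 == 0))
})

test_that("inflection locator interpolates the first persistent crossing", {
  pr <- fake_profile(c(1, 2, 3, 4), c(1, 0.5, -0.2, -0.5))
  expect_equal(find_inflection(pr, k = 1), 2 + 0.5 / 0.7,
               tolerance = 1e-12)
  # all-negative profile: no inflection (type II signature)
  expect_true(is.na(find_inflection(fake_profile(1:10, rep(-1, 10)))))
  # single-point sign flip is suppressed by the persistence rule
  noisy <- rep(-1, 20); noisy[8] <- 1e-14
  expect_true(is.na(find_inflection(fake_profile(1:20, noisy), k = 5)))
  # two crossings: the first (lowest offered) is reported
  two <- c(rep(1, 6), rep(-1, 6), rep(1, 6), rep(-1, 6))
  expect_equal(find_inflection(fake_profile(1:24, two), k = 3), 6.5)
  # logistic curve: analytic inflection at the midpoint
  x <- seq(0, 10, by = 0.01)
  pr <- finite_differences(fr_curve(x, 1 / (1 + exp(-(x - 5)))))
  expect_equal(find_inflection(pr), 5, tolerance = 0.01)
})

test_that("classifier reproduces the canonical shape controls", {
  offered <- seq(1, 200, by = 0.5)
  # disk equation: saturating, concave everywhere -> type II
  disk <- fr_curve(offered, holling_closed_form(0.1, 0.1, offered, 1))
  expect_equal(classify_curve(disk)$shape, "TYPE_II")
  pr <- finite_differences(disk)
  expect_true(all(pr$d2 < 0))
  expect_true(all(diff(abs(pr$d2)) < 0))      # |d2| decays toward zero
  # linear curve -> type I, no inflection
  lin <- classify_curve(fr_curve(offered, 0.5 * offered))
  expect_equal(lin$shape, "TYPE_I")
  expect_true(is.na(lin$inflection_offered))
  # attack learning -> sigmoid type III with an inflection point
  p <- fr_predator(a0 = 0.2, am = 1, la = 0.2, h0 = 0.1, hm = 0.1)
  cls <- classify_curve(response_curve(p, offered, fr_config()))
  expect_equal(cls$shape, "TYPE_III")
  expect_false(is.na(cls$inflection_offered))
  expect_gt(cls$max_normalized_d2, 0.05)
})

test_that("attack learning makes the response convex at low density", {
  offered <- seq(1, 200, by = 0.5)
  for (la in c(0.2, 0.5, 1)) for (a0 in c(0.05, 0.2)) {
    p <- fr_predator(a0 = a0, am = 1, la = la, h0 = 0.1, hm = 0.1)
    # convex below the inflection; strong learning pulls the inflection
    # toward the grid start, so only the lowest offered values are probed
    pr <- finite_differences(response_curve(p, offered, fr_config()))
    expect_true(all(pr$d2[1:3] > 0))
  }
})

test_that("exact disk-equation curves are never classified sigmoid or linear", {
  offered <- seq(1, 200, by = 0.5)
  for (a in c(0.05, 0.2, 1)) for (h in c(0.05, 0.2, 1)) {
    # a h Dmax >> 1: deep saturation, unambiguous type II signature
    cls <- classify_curve(fr_curve(offered,
                                   holling_closed_form(a, h, offered, 1)))
    expect_false(cls$shape %in% c("TYPE_III", "TYPE_I"),
                 info = sprintf("a=%g h=%g", a, h))
  }
})

test_that("classification is stable to grid refinement away from boundaries", {
  probes <- list(
    list(p = fr_predator(0.1, 1, 0.5, 0.1, 0.1, 0), want = "TYPE_III"),
    list(p = fr_predator(0.8, 1, 0.05, 0.1, 0.1, 0), want = "TYPE_II"),
    list(p = fr_predator(0.1, 0.1, 0, 1, 0.05, 0.3), want = "TYPE_II"))
  for (pb in probes) {
    for (step in c(0.5, 0.25)) {
      cls <- classify_curve(response_curve(pb$p, seq(1, 200, by = step),
                                           fr_config()))
      expect_equal(cls$shape, pb$want)
    }
    # classification is also insensitive to the integration step: RK4 at
    # 1/64 is already converged far below the classifier thresholds
    cls64 <- classify_curve(response_curve(pb$p, seq(1, 200, by = 0.5),
                                           fr_config(dt = 1 / 64)))
    expect_equal(cls64$shape, pb$want)
  }
})

test_that("threshold validation and smoothing behave", {
  x <- seq(1, 50)
  pr <- finite_differences(fr_curve(x, sqrt(x)))
  expect_error(classify_response(pr, eps_lin = 0.05, eps_pos = 0.02),
               "eps_lin")
  expect_error(smooth_curve(fr_curve(x, sqrt(x)), window = 4), "odd")
  set.seed(1)
  noisy <- fr_curve(x, pmax(0.5 * x + rnorm(50, sd = 0.05), 0))
  sm <- smooth_curve(noisy, window = 7)
  expect_lt(max(abs(finite_differences(sm)$d2)),
            max(abs(finite_differences(noisy)$d2)))
  expect_equal(nrow(sm), nrow(noisy))
})
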