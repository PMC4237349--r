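# exact linear O2 decline: slope mg L^-1 h^-1, over half an hour
linear_trace <- function(slope = -0.5, chamber = 127, mass = 0.65,
                         speed = 0.5, n = 31) {
  tt <- seq(0, 0.5, length.out = n)
  o2_trace(tt, 7.6 + slope * tt, chamber, mass, speed)
}

test_that("MO2 from an exact linear trace matches the volume arithmetic", {
  s <- mo2_from_trace(linear_trace())
  expect_equal(s$mo2, 0.5 * (127 - 0.65) / 0.65, tolerance = 1e-10)
  expect_equal(s$mo2, 97.2, tolerance = 1e-3)
  expect_equal(s$r2, 1)
  expect_true(s$accepted)
  # effective-volume convention is configurable
  s0 <- mo2_from_trace(linear_trace(), fish_volume_per_kg = 0)
  expect_equal(s0$mo2, 0.5 * 127 / 0.65, tolerance = 1e-10)
})

test_that("trace validation rejects malformed input", {
  expect_error(o2_trace(1:4, c(7, 6, 5, 4), 127, 0.65, 0.5), "5 samples")
  expect_error(o2_trace(c(0, 1, 1, 2, 3), rep(7, 5), 127, 0.65, 0.5),
               "increasing")
  expect_error(o2_trace(0:4, rep(7, 5), 0.5, 0.65, 0.5), "volume")
})

test_that("white-noise traces with no true decline are rejected", {
  set.seed(402)
  rejected <- replicate(500, {
    tt <- seq(0, 0.5, length.out = 31)
    tr <- o2_trace(tt, 7.6 + rnorm(31, 0, 0.05), 127, 0.65, 0.5)
    !mo2_from_trace(tr)$accepted
  })
  expect_gte(mean(rejected), 0.90)
})

test_that("solid-blocking correction follows the fractional-error form", {
  ctx <- blocking_context(fish_area = 25, tunnel_area = 100)
  expect_equal(fractional_error(ctx), 0.8 * 0.5 * 0.25^1.5)
  expect_equal(fractional_error(ctx), 0.05)
  expect_equal(correct_speed(0.6, ctx), 0.63)
  # no blockage, no correction
  expect_equal(correct_speed(0.6, blocking_context(0, 100)), 0.6)
  expect_error(blocking_context(fish_area = 100, tunnel_area = 100),
               "smaller")
})

test_that("blocking error grows with fish area and preserves speed order", {
  ao <- seq(0, 90, 10)
  eps <- vapply(ao, function(a)
    fractional_error(blocking_context(a, 100)), 0)
  expect_true(all(diff(eps) > 0))
  ctx <- blocking_context(50, 100)
  u <- seq(0.1, 1, 0.1)
  expect_true(all(diff(correct_speed(u, ctx)) > 0))
  expect_true(all(correct_speed(u, ctx) >= u))
})

test_that("default blocking context gives the expected few-percent correction", {
  expect_equal(fractional_error(blocking_context()), 0.049, tolerance = 0.02)
})

test_that("exponential metabolic model recovers exact parameters", {
  u <- seq(0.3, 0.9, 0.1)
  m <- fit_metabolic_model(u, 40.58 * exp(1.4706 * u))
  expect_equal(coef(m), c(smr = 40.58, c = 1.4706), tolerance = 1e-6)
  expect_equal(m$fit_r2, 1, tolerance = 1e-9)
  expect_error(fit_metabolic_model(c(0.3, 0.5), c(60, 80)), "3 distinct")
})

test_that("a single high-speed sample can be folded into the fit", {
  # sparse design: three low speeds plus one isolated point at 0.6
  u <- c(0.3, 0.4, 0.5, 0.6)
  m <- fit_metabolic_model(u, 79.65 * exp(u / 0.47))
  expect_equal(m$smr, 79.65, tolerance = 1e-6)
  expect_equal(uopt(m), 0.47, tolerance = 1e-6)
})

test_that("Uopt is the reciprocal exponent and matches a grid search", {
  m <- list(smr = 40.58, c = 1.4706)
  expect_equal(uopt(m), 1 / 1.4706)
  expect_equal(uopt(m), 0.68, tolerance = 1e-2)
  expect_equal(uopt(list(smr = 40.58, c = 2 * 1.4706)), uopt(m) / 2)
  # numerical oracle: dense grid minimisation of the cost of transport
  grid <- seq(0.01, 2, by = 1e-3)
  u_star <- grid[which.min(cot(m, grid))]
  expect_lt(abs(u_star - uopt(m)), 1e-3)
  expect_error(uopt(list(smr = 40, c = -1)), "positive")
})

test_that("cost of transport has the closed-form minimum", {
  m <- list(smr = 40.58, c = 1.4706)
  expect_equal(cot(m, 1 / m$c), m$smr * m$c * exp(1) / 3.6)
  expect_equal(cot_min(m), 45.06, tolerance = 1e-3)
  expect_equal(cot_min(m), cot(m, uopt(m)))
  # unique minimum and divergence at low speed
  u <- setdiff(seq(0.05, 2, 0.05), uopt(m))
  expect_true(all(cot(m, u) > cot_min(m)))
  expect_gt(cot(m, 1e-4), 1e4)
  # doubling SMR doubles the minimum cost
  expect_equal(cot_min(list(smr = 2 * m$smr, c = m$c)), 2 * cot_min(m))
  expect_error(cot(m, 0), "positive")
})

test_that("cost of transport is convex in speed", {
  m <- list(smr = 40.58, c = 1.4706)
  u <- seq(0.05, 2, length.out = 400)
  y <- cot(m, u)
  expect_true(all(diff(diff(y)) > 0))
})

test_that("acceptance filter honours its thresholds", {
  set.seed(403)
  for (i in 1:50) {
    tt <- seq(0, 0.5, length.out = 31)
    tr <- o2_trace(tt, 7.6 - 0.4 * tt + rnorm(31, 0, 0.05), 127, 0.65, 0.5)
    s <- mo2_from_trace(tr, min_r2 = 0.6, alpha = 0.05)
    if (s$accepted) {
      expect_gte(s$r2, 0.6)
      expect_lt(s$p_value, 0.05)
      expect_lt(s$slope, 0)
    }
  }
})
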