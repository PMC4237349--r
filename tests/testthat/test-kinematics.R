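sine_track <- function(freq = 2.5, half_amp = 0.038, duration = 20,
                       rate = 30, phase = 0, offset = 0, noise = 0,
                       speed = 0.65) {
  tt <- seq(0, duration - 1 / rate, by = 1 / rate)
  y <- offset + half_amp * sin(2 * pi * freq * tt + phase)
  if (noise > 0) y <- y + rnorm(length(tt), 0, noise)
  landmark_track(tt, y, frame_rate = rate, swim_speed = speed)
}

test_that("segment selection is block-wise, disjoint and reproducible", {
  w <- select_segments(1200, 20, 3, seed = 11)
  expect_equal(nrow(w), 3)
  # one window inside each 400-s block
  expect_true(all(w$start >= c(0, 400, 800) & w$end <= c(400, 800, 1200)))
  expect_true(all(w$end - w$start == 20))
  # disjoint
  o <- order(w$start)
  expect_true(all(w$start[o][-1] >= w$end[o][-3]))
  expect_identical(w, select_segments(1200, 20, 3, seed = 11))
  expect_error(select_segments(1200, 500, 3), "exceeds")
})

test_that("segment selection samples slots uniformly", {
  slots <- sapply(1:1000, function(s)
    select_segments(1200, 20, 3, seed = s)$start[1] / 20 + 1)
  freq <- tabulate(slots, nbins = 20) / 1000
  expect_true(all(abs(freq - 0.05) < 0.02))
})

test_that("tail-beat frequency counts cycles of a sinusoid", {
  expect_equal(tailbeat_frequency(sine_track(2.5)), 2.5, tolerance = 0.011)
  # constant offset and slow drift do not bias the count
  tr <- sine_track(2.5, offset = 0.4)
  expect_equal(tailbeat_frequency(tr),
               tailbeat_frequency(sine_track(2.5)), tolerance = 1e-9)
  flat <- landmark_track(seq(0, 1, 1 / 30), rep(0.1, 31), 30, 0.5)
  expect_error(tailbeat_frequency(flat), "flat signal")
})

test_that("frequency estimation tolerates realistic noise", {
  set.seed(404)
  ok <- replicate(200, {
    tr <- sine_track(2.5, noise = 0.0038)  # 10% of the half-amplitude
    abs(tailbeat_frequency(tr) - 2.5) <= 0.1
  })
  expect_gte(mean(ok), 0.95)
})

test_that("amplitude is peak-to-peak in cm and scales linearly", {
  tr <- sine_track(2.5, half_amp = 0.038)
  expect_equal(lateral_amplitude(tr), 7.6, tolerance = 1e-3)
  tr2 <- sine_track(2.5, half_amp = 0.076)
  expect_equal(lateral_amplitude(tr2), 2 * lateral_amplitude(tr),
               tolerance = 1e-6)
  flat <- landmark_track(seq(0, 1, 1 / 30), rep(0.1, 31), 30, 0.5)
  expect_equal(lateral_amplitude(flat), 0)
  # offset-invariant
  expect_equal(lateral_amplitude(sine_track(2.5, offset = 1)),
               lateral_amplitude(tr), tolerance = 1e-9)
})

test_that("wave speed is separation over cross-correlation lag", {
  rate <- 30
  front <- sine_track(2.0, rate = rate)
  rear <- sine_track(2.0, rate = rate, phase = -2 * pi * 2.0 * 0.1)  # 0.1 s lag
  expect_equal(wave_speed(front, rear, 0.1), 1.0, tolerance = 0.05)
  expect_error(wave_speed(front, front, 0.1), "zero phase lag")
  flat <- landmark_track(seq(0, 19, 1 / rate), rep(0, 571), rate, 0.5)
  expect_error(wave_speed(flat, flat, 0.1), "flat|lag")
})

test_that("wave speed recovers a travelling wave built from control kinematics", {
  # W = 0.23 + 1.05 U at U = 0.65 -> 0.9125 m s^-1 between sites A and B
  u <- 0.65
  w_true <- 0.23 + 1.05 * u
  f <- 1.26 + 2.15 * u
  bl <- 0.657
  sep <- (0.35 - 0.125) * bl
  tt <- seq(0, 20 - 1 / 30, by = 1 / 30)
  front <- landmark_track(tt, 0.004 * sin(2 * pi * f * (tt - 0.125 * bl / w_true)),
                          30, u)
  rear <- landmark_track(tt, 0.0125 * sin(2 * pi * f * (tt - 0.35 * bl / w_true)),
                         30, u)
  expect_equal(wave_speed(front, rear, sep), 0.91, tolerance = 0.05)
})

test_that("Strouhal number is a f / U with the expected control magnitude", {
  # control regression f at 0.65 m s^-1 with 7.6 cm peak-to-peak amplitude
  expect_equal(strouhal(0.076, 2.66, 0.65), 0.311, tolerance = 1e-3)
  expect_equal(strouhal(0.076, 2 * 2.66, 0.65), 2 * strouhal(0.076, 2.66, 0.65))
  expect_equal(strouhal(0.2, 5, 1), 1)
  expect_error(strouhal(0.076, 2.66, 0), "positive")
})

test_that("control Strouhal numbers sit in the published band near Uopt", {
  for (u in c(0.6, 0.65, 0.7)) {
    st <- strouhal(0.076, 1.26 + 2.15 * u, u)
    expect_true(abs(st - 0.32) <= 0.12)
  }
})

test_that("kinematic speed regressions recover published control lines", {
  u <- seq(0.3, 0.9, 0.1)
  ff <- fit_kinematic(u, 1.26 + 2.15 * u, "f")
  expect_equal(coef(ff), c(intercept = 1.26, slope = 2.15), tolerance = 1e-10)
  wf <- fit_kinematic(u, 0.23 + 1.05 * u, "W")
  expect_equal(coef(wf), c(intercept = 0.23, slope = 1.05), tolerance = 1e-10)
  const <- fit_kinematic(u, rep(7.6, length(u)), "a")
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_error(fit_kinematic(c(0.3, 0.5), c(1, 2)), "3 distinct")
})

test_that("the body wave always outruns the fish over the tested speeds", {
  u <- seq(0.3, 0.9, 0.01)
  w <- 0.23 + 1.05 * u
  expect_true(all(u / w < 1))
})
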