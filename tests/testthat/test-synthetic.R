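test_that("cohort draws are reproducible and respect degenerate spreads", {
  cfg <- cohort_config(n_eels = 6, seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # zero spread collapses every eel onto the population mean
  cfg0 <- cohort_config(n_eels = 4, smr = c(40.58, 0), uopt = c(0.68, 0),
                        seed = 1)
  co <- generate_cohort(cfg0)
  expect_true(all(co$smr == 40.58))
  expect_true(all(co$uopt == 0.68))
  expect_equal(co$c, rep(1 / 0.68, 4))
  expect_error(cohort_config(smr = c(-5, 1)), "positive")
})

test_that("cohort means settle on the configured population values", {
  smr_means <- vapply(1:100, function(s)
    mean(generate_cohort(cohort_config(seed = s))$smr), 0)
  # truncated-normal draws around 40.58 with sd 18.24, 100 cohorts of 8:
  # grand mean within 2 SE of the target (truncation inflates it slightly)
  se <- 6.45 * sqrt(8) / sqrt(800)
  expect_lt(abs(mean(smr_means) - 40.58), 2 * se + 2)
})

test_that("noise-free O2 traces return the exact metabolic curve", {
  cfg <- cohort_config(mo2_cv = 0, o2_sd = 0, seed = 9)
  co <- generate_cohort(cfg)
  eel <- co[1, ]
  trs <- generate_o2_traces(eel, drag = 0, site = "A", config = cfg)
  for (tr in trs) {
    s <- mo2_from_trace(tr)
    expect_true(s$accepted)
    expect_equal(s$mo2, eel$smr * exp(eel$c * tr$tunnel_speed),
                 tolerance = 1e-9)
    expect_equal(s$mo2, attr(tr, "true_mo2"), tolerance = 1e-9)
  }
})

test_that("simulated trace quality matches swim-tunnel slope fits", {
  cfg <- cohort_config(seed = NULL)
  set.seed(408)
  co <- generate_cohort(cohort_config(n_eels = 40, seed = NULL))
  r2 <- unlist(lapply(seq_len(nrow(co)), function(i) {
    trs <- generate_o2_traces(co[i, ], config = cfg)
    vapply(trs, function(tr) mo2_from_trace(tr)$r2, 0)
  }))
  expect_equal(mean(r2), 0.857, tolerance = 0.05 / 0.857)
})

test_that("added drag raises generated transport costs and lowers Ucrit", {
  cfg <- cohort_config(seed = 10)
  co <- generate_cohort(cfg)
  eel <- co[1, ]
  ctl <- condition_energetics(eel, 0, "A", cfg)
  lrg <- condition_energetics(eel, 0.2, "A", cfg)
  expect_gt(lrg$cotmin_eff, ctl$cotmin_eff)
  expect_lt(lrg$ucrit_true, ctl$ucrit_true)
  expect_lt(lrg$uopt_eff, ctl$uopt_eff)       # Uopt drops only at 0.2 N
  mid <- condition_energetics(eel, 0.1, "A", cfg)
  expect_equal(mid$uopt_eff, ctl$uopt_eff)
  # site B is strictly worse than site A at the same drag
  mid_b <- condition_energetics(eel, 0.1, "B", cfg)
  expect_gt(mid_b$cotmin_eff, mid$cotmin_eff)
  expect_lt(mid_b$ucrit_true, mid$ucrit_true)
})

test_that("fatigue logs round-trip through the Brett formula", {
  cfg <- cohort_config(effect_sd = 0, seed = 11)
  co <- generate_cohort(cfg)
  for (i in 1:3) {
    eel <- co[i, ]
    lg <- generate_ucrit_log(eel, drag = 0, site = "A", config = cfg)
    res <- ucrit_from_log(lg$step_speed_m_s, lg$completed_min)
    expect_equal(res$u_crit, eel$ucrit_baseline, tolerance = 1e-9)
    expect_equal(res$u_crit, attr(lg, "true_ucrit"), tolerance = 1e-9)
  }
  # stochastic ordering under drag
  cfg2 <- cohort_config(seed = NULL)
  set.seed(409)
  co2 <- generate_cohort(cohort_config(n_eels = 30, seed = NULL))
  u0 <- vapply(seq_len(nrow(co2)), function(i)
    attr(generate_ucrit_log(co2[i, ], 0, "A", cfg2), "true_ucrit"), 0)
  u2 <- vapply(seq_len(nrow(co2)), function(i)
    attr(generate_ucrit_log(co2[i, ], 0.2, "A", cfg2), "true_ucrit"), 0)
  expect_gt(mean(u0) - mean(u2), 0.2)
})

test_that("noise-free kinematic tracks return the generating wave", {
  cfg <- cohort_config(kinematic_sd = 0, seed = 12)
  co <- generate_cohort(cfg)
  eel <- co[1, ]
  kin <- generate_kinematics(eel, speeds = 0.65, config = cfg)
  k <- kin[[1]]
  expect_equal(tailbeat_frequency(k$tail), attr(k, "true_f"),
               tolerance = 0.03 / attr(k, "true_f"))
  expect_equal(lateral_amplitude(k$tail), eel$amp_tail, tolerance = 1e-3)
  expect_equal(wave_speed(k$site_a, k$site_b, 0.225 * eel$body_length),
               attr(k, "true_w"), tolerance = 0.05)
})

test_that("recovered Strouhal numbers sit in the control band and rise at site B", {
  cfg <- cohort_config(seed = NULL)
  set.seed(408)
  co <- generate_cohort(cohort_config(seed = NULL))
  st_of <- function(drag, site) {
    vapply(seq_len(nrow(co)), function(i) {
      k <- generate_kinematics(co[i, ], speeds = 0.65, drag = drag,
                               site = site, config = cfg)[[1]]
      strouhal(lateral_amplitude(k$tail) / 100,
               tailbeat_frequency(k$tail), 0.65)
    }, 0)
  }
  st_ctrl <- st_of(0, "A")
  expect_true(abs(mean(st_ctrl) - 0.32) <= 0.12)
  st_b <- st_of(0.1, "B")
  expect_gt(mean(st_b), mean(st_ctrl))
})

test_that("the study bundle is seed-stable and internally consistent", {
  cfg <- cohort_config(n_eels = 2, seed = 77)
  conds <- default_conditions()[c(1, 3), ]
  b1 <- simulate_swim_study(cfg, conditions = conds, kinematics = FALSE)
  b2 <- simulate_swim_study(cfg, conditions = conds, kinematics = FALSE)
  expect_identical(b1$traces, b2$traces)
  expect_identical(b1$steps, b2$steps)
  expect_identical(b1$truth, b2$truth)
  expect_setequal(unique(b1$truth$condition), conds$condition)
  expect_equal(nrow(b1$truth), 4)
})
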