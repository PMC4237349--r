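test_that("percent effects are paired, signed changes against control", {
  ctrl <- data.frame(eel_id = c("a", "b"), ucrit = c(1.0, 0.9),
                     cotmin = c(50, 68.83))
  trt <- data.frame(eel_id = c("a", "b"), drag = 0.1,
                    ucrit = c(0.7, 0.9), cotmin = c(50, 111.76))
  eff <- percent_effects(ctrl, trt)
  expect_equal(eff$red_pct_ucrit, c(30, 0))
  expect_equal(eff$inc_pct_cotmin[1], 0)
  # published intermediate-A vs intermediate-B COTmin step is ~62-63%
  expect_equal(eff$inc_pct_cotmin[2], 62.4, tolerance = 1e-3)
  expect_error(percent_effects(ctrl, transform(trt, eel_id = c("a", "z"))),
               "missing from control")
  expect_error(percent_effects(transform(ctrl, ucrit = c(0, 1)), trt),
               "positive")
})

test_that("through-origin quadratic recovers published coefficient pairs", {
  fd <- rep(c(0.05, 0.1, 0.2), each = 8)
  eff_u <- data.frame(drag = fd, red_pct_ucrit = 102.8 * fd + 527.7 * fd^2)
  fit_u <- fit_impairment(eff_u, "ucrit")
  expect_equal(coef(fit_u), c(lin = 102.8, quad = 527.7), tolerance = 1e-8)
  eff_c <- data.frame(drag = fd, inc_pct_cotmin = -8.92 * fd + 2687 * fd^2)
  fit_c <- fit_impairment(eff_c, "cotmin")
  expect_equal(coef(fit_c), c(lin = -8.92, quad = 2687), tolerance = 1e-8)
  # mean-per-level mode agrees on noise-free data
  fit_m <- fit_impairment(eff_u, "ucrit", pooled = FALSE)
  expect_equal(coef(fit_m), coef(fit_u), tolerance = 1e-8)
  expect_error(fit_impairment(data.frame(drag = rep(0.1, 4),
                                         red_pct_ucrit = 1:4), "ucrit"),
               "2 distinct")
})

test_that("noisy effect fits recover coefficients within 3 SE almost always", {
  fd <- rep(c(0.05, 0.1, 0.2), each = 8)
  truth <- 102.8 * fd + 527.7 * fd^2
  set.seed(405)
  cover <- replicate(500, {
    eff <- data.frame(drag = fd, red_pct_ucrit = truth + rnorm(24, 0, 10))
    fit <- fit_impairment(eff, "ucrit")
    abs(fit$lin_coeff - 102.8) < 3 * fit$coeff_se["lin"] &&
      abs(fit$quad_coeff - 527.7) < 3 * fit$coeff_se["quad"]
  })
  expect_gte(mean(cover), 0.95)
})

test_that("the evaluation tool reproduces the published worked example", {
  expect_equal(predict_impairment(102.8, 527.7, 0.159), 29.68,
               tolerance = 1e-3)
  expect_equal(predict_impairment(-8.92, 2687, 0.159), 66.51,
               tolerance = 1e-3)
  expect_equal(predict_impairment(102.8, 527.7, 0), 0)
  expect_warning(predict_impairment(102.8, 527.7, 0.3), "extrapolating")
})

test_that("prediction through the origin holds for any coefficients", {
  set.seed(406)
  for (i in 1:20) {
    a <- runif(1, -100, 200); b <- runif(1, -500, 3000)
    expect_identical(predict_impairment(a, b, 0), 0)
  }
})

test_that("site-B increments are additive and site A is neutral", {
  sc_b <- tag_scenario(0.159, "B")
  expect_equal(combined_site_effect(29.68, sc_b, "ucrit"), 44.68)
  expect_equal(combined_site_effect(66.51, sc_b, "cotmin"), 129.51)
  sc_a <- tag_scenario(0.159, "A")
  expect_equal(combined_site_effect(29.68, sc_a, "ucrit"), 29.68)
  ev <- evaluate_tag(sc_b)
  expect_equal(ev$ucrit$total, 45, tolerance = 0.5 / 45)
  expect_equal(ev$cotmin$total, 130, tolerance = 0.5 / 130)
  expect_false(evaluate_tag(tag_scenario(0.1, "A"))$extrapolation_flag)
})

test_that("endpoint curves agree at low drag and diverge beyond 0.1 N", {
  fits <- reference_impairment_fits()
  div <- endpoint_divergence(fits$ucrit, fits$cotmin,
                             drag_grid = c(0.05, 0.2))
  expect_equal(div$pred_ucrit, c(6.46, 41.67), tolerance = 1e-3)
  expect_equal(div$pred_cotmin, c(6.27, 105.69), tolerance = 1e-3)
  expect_lt(abs(div$difference[1]), 1)
  expect_gt(abs(div$difference[2]), 50)
  # identical fits never diverge
  same <- endpoint_divergence(fits$ucrit, fits$ucrit,
                              drag_grid = seq(0.02, 0.2, 0.02))
  expect_true(all(same$difference == 0))
})

test_that("pipeline closure: simulated effects converge to the worked example", {
  # cohort whose true responses follow the published coefficients; as the
  # response noise vanishes the fitted tool reproduces the 0.159 N example
  cfg <- cohort_config(effect_sd = 1e-4, mo2_cv = 0, o2_sd = 0,
                       seed = NULL)
  set.seed(407)
  co <- generate_cohort(cfg)
  ctrl <- NULL; trt <- NULL
  for (i in seq_len(nrow(co))) {
    eel <- co[i, ]
    e0 <- condition_energetics(eel, 0, "A", cfg)
    lg0 <- generate_ucrit_log(eel, 0, "A", cfg)
    ctrl <- rbind(ctrl, data.frame(eel_id = eel$eel_id,
                                   ucrit = attr(lg0, "true_ucrit"),
                                   cotmin = e0$cotmin_eff))
    for (fd in c(0.05, 0.1, 0.2)) {
      et <- condition_energetics(eel, fd, "A", cfg)
      lg <- generate_ucrit_log(eel, fd, "A", cfg)
      trt <- rbind(trt, data.frame(eel_id = eel$eel_id, drag = fd,
                                   ucrit = attr(lg, "true_ucrit"),
                                   cotmin = et$cotmin_eff))
    }
  }
  eff <- percent_effects(ctrl, trt)
  fit <- fit_impairment(eff, "ucrit")
  expect_equal(predict(fit, 0.159), 29.68, tolerance = 2 / 29.68)
})
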