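# Shared simulation harness for end-to-end recovery tests.

# Fit one eel's metabolic model from simulated O2 traces, mirroring the
# pipeline stages (trace -> slope filter -> exponential fit). Returns NULL
# when the eel would be excluded (too few accepted samples, failed fit, or
# a cost-of-transport minimum outside the tested speed range).
fit_eel_energetics <- function(eel, drag, site, cfg, min_r2 = 0.85,
                               speed_range = c(0.3, 0.9)) {
  trs <- generate_o2_traces(eel, drag = drag, site = site, config = cfg)
  samps <- lapply(trs, mo2_from_trace, min_r2 = min_r2)
  acc <- vapply(samps, `[[`, TRUE, "accepted")
  if (sum(acc) < 3) return(NULL)
  m <- tryCatch(
    fit_metabolic_model(vapply(samps[acc], `[[`, 0, "speed"),
                        vapply(samps[acc], `[[`, 0, "mo2")),
    error = function(e) NULL)
  if (is.null(m) || m$c <= 0) return(NULL)
  u <- uopt(m)
  if (u < speed_range[1] || u > speed_range[2]) return(NULL)
  list(smr = m$smr, uopt = u, cotmin = cot_min(m))
}

# Both energetic endpoints for one eel x condition, with MO2-sample-level
# noise (multiplicative CV) and a stochastic fatigue log.
simulate_endpoints <- function(eel, drag, site, cfg) {
  eff <- condition_energetics(eel, drag, site, cfg)
  u <- seq(0.3, 0.9, 0.1)
  u <- if (sum(u <= eff$ucrit_true + 1e-9) >= 3)
    u[u <= eff$ucrit_true + 1e-9] else u[1:3]
  sdlog <- sqrt(log(1 + cfg$mo2_cv^2))
  mo2 <- eff$smr_eff * exp(eff$c_eff * u) *
    stats::rlnorm(length(u), -sdlog^2 / 2, sdlog)
  m <- tryCatch(fit_metabolic_model(u, mo2), error = function(e) NULL)
  if (is.null(m) || m$c <= 0) return(NULL)
  lg <- generate_ucrit_log(eel, drag, site, cfg)
  res <- ucrit_from_log(lg$step_speed_m_s, lg$completed_min)
  c(ucrit = res$u_crit, cotmin = cot_min(m))
}

# Control + treated endpoint tables for one simulated cohort at the three
# standard dummy drags, all at site A.
simulate_effect_tables <- function(cfg, drags = c(0.05, 0.1, 0.2)) {
  co <- generate_cohort(cfg)
  ctrl <- NULL; trt <- NULL
  for (i in seq_len(nrow(co))) {
    e0 <- simulate_endpoints(co[i, ], 0, "A", cfg)
    if (is.null(e0)) next
    ctrl <- rbind(ctrl, data.frame(eel_id = co$eel_id[i],
                                   ucrit = e0[["ucrit"]],
                                   cotmin = e0[["cotmin"]]))
    for (fd in drags) {
      et <- simulate_endpoints(co[i, ], fd, "A", cfg)
      if (is.null(et)) next
      trt <- rbind(trt, data.frame(eel_id = co$eel_id[i], drag = fd,
                                   ucrit = et[["ucrit"]],
                                   cotmin = et[["cotmin"]]))
    }
  }
  list(control = ctrl, treated = trt)
}
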