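#' Configuration of a virtual eel cohort
#'
#' Defines the population a synthetic swim-trial study draws from. Defaults
#' describe a cohort of eight farmed female silver eels (~650 g, ~0.66 m)
#' with control energetics SMR ~ 40.6 mgO2 kg^-1 h^-1 and Uopt ~ 0.68
#' m s^-1, control kinematics f = 1.26 + 2.15 U and W = 0.23 + 1.05 U, and
#' drag-impairment responses following the through-origin quadratics with
#' a = 102.8, b = 527.7 (percent Ucrit reduction) and a = -8.92, b = 2687
#' (percent COTmin increase). Between-individual spreads are population
#' standard deviations obtained from published standard errors of the mean
#' as SE * sqrt(8).
#'
#' All `c(mean, sd)` pairs are sampled as truncated (positive) normals.
#'
#' @param n_eels cohort size.
#' @param body_mass `c(mean, sd)` body mass (kg).
#' @param body_length `c(mean, sd)` body length (m).
#' @param fish_area `c(mean, sd)` maximum cross-sectional area (mm^2).
#' @param smr `c(mean, sd)` standard metabolic rate (mgO2 kg^-1 h^-1).
#' @param uopt `c(mean, sd)` optimal swimming speed (m s^-1).
#' @param ucrit_baseline `c(mean, sd)` untagged critical swimming speed
#'   (m s^-1).
#' @param f_intercept,f_slope `c(mean, sd)` of the tail-beat-frequency speed
#'   regression (Hz; Hz per m s^-1).
#' @param w_intercept,w_slope `c(mean, sd)` of the body-wave-speed
#'   regression (m s^-1; dimensionless slope).
#' @param amp_tail,amp_a,amp_b `c(mean, sd)` peak-to-peak amplitudes (cm) at
#'   the tail tip, site A (0.125 bl) and site B (0.35 bl).
#' @param impair_ucrit `c(a, b)` drag-impairment coefficients for percent
#'   Ucrit reduction (% N^-1, % N^-2).
#' @param impair_cotmin `c(a, b)` coefficients for percent COTmin increase.
#' @param site_ucrit_increment,site_cotmin_increment extra percentage points
#'   when attached at site B.
#' @param uopt_large_ratio factor applied to Uopt at drags of 0.2 N and
#'   above (Uopt is drag-insensitive below that; default 0.47/0.68).
#' @param mo2_cv multiplicative coefficient of variation of per-speed MO2.
#' @param o2_sd additive noise sd on O2-trace samples (mg L^-1); the default
#'   0.0145 makes simulated slope fits average r^2 ~ 0.86 across the cohort
#'   and speed range, matching published swim-tunnel fit quality.
#' @param kinematic_sd lateral digitization noise sd (m).
#' @param effect_sd lognormal sd of per-individual condition responses.
#' @param chamber_volume respirometer volume (L).
#' @param o2_start starting O2 concentration of each trace (mg L^-1).
#' @param seed integer seed used by [generate_cohort()] and
#'   [simulate_swim_study()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_eels = 8,
                          body_mass = c(0.6494, 0.1312 * sqrt(8)),
                          body_length = c(0.657, 0.042 * sqrt(8)),
                          fish_area = c(150.5, 9.6 * sqrt(8)),
                          smr = c(40.58, 6.45 * sqrt(8)),
                          uopt = c(0.68, 0.03 * sqrt(8)),
                          ucrit_baseline = c(0.87, 0.03 * sqrt(8)),
                          f_intercept = c(1.26, 0.14 * sqrt(8)),
                          f_slope = c(2.15, 0.16 * sqrt(8)),
                          w_intercept = c(0.23, 0.05 * sqrt(8)),
                          w_slope = c(1.05, 0.11 * sqrt(8)),
                          amp_tail = c(7.6, 1.6 * sqrt(8)),
                          amp_a = c(0.8, 0.2 * sqrt(8)),
                          amp_b = c(2.5, 1.2 * sqrt(8)),
                          impair_ucrit = c(102.8, 527.7),
                          impair_cotmin = c(-8.92, 2687),
                          site_ucrit_increment = 15,
                          site_cotmin_increment = 63,
                          uopt_large_ratio = 0.47 / 0.68,
                          mo2_cv = 0.10,
                          o2_sd = 0.0145,
                          kinematic_sd = 0.002,
                          effect_sd = 0.05,
                          chamber_volume = 127,
                          o2_start = 7.6,
                          seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("body_mass", "body_length", "fish_area", "smr", "uopt",
               "ucrit_baseline", "f_intercept", "f_slope", "w_intercept",
               "w_slope", "amp_tail", "amp_a", "amp_b")) {
    v <- cfg[[nm]]
    if (length(v) != 2 || v[2] < 0)
      stop("`", nm, "` must be c(mean, sd) with sd >= 0", call. = FALSE)
    if (v[1] <= 0)
      stop("`", nm, "` mean must be positive (truncated-normal draw)",
           call. = FALSE)
  }
  if (n_eels < 1) stop("`n_eels` must be >= 1", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: %d eels, SMR %.2f±%.2f, Uopt %.2f±%.3f, seed %s\n",
              x$n_eels, x$smr[1], x$smr[2], x$uopt[1], x$uopt[2],
              as.character(x$seed)))
  invisible(x)
}

# positive truncated-normal draws by rejection
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] <= 0]
  }
  out
}

#' Draw a virtual cohort
#'
#' Samples per-individual parameters (morphometrics, energetics, baseline
#' kinematic coefficients) from the population described by a
#' [cohort_config()]. The metabolic exponent is derived as `c = 1/uopt`.
#'
#' @param config a [cohort_config()].
#' @return a data frame of class `virtual_cohort`, one row per eel.
#' @examples
#' generate_cohort(cohort_config(n_eels = 4, seed = 7))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  draw <- function() {
    n <- config$n_eels
    g <- function(p) rtnorm_pos(n, p[1], p[2])
    d <- data.frame(
      eel_id = sprintf("eel%02d", seq_len(n)),
      body_mass = g(config$body_mass),
      body_length = g(config$body_length),
      fish_area = g(config$fish_area),
      smr = g(config$smr),
      uopt = g(config$uopt),
      ucrit_baseline = g(config$ucrit_baseline),
      f_intercept = g(config$f_intercept),
      f_slope = g(config$f_slope),
      w_intercept = g(config$w_intercept),
      w_slope = g(config$w_slope),
      amp_tail = g(config$amp_tail),
      amp_a = g(config$amp_a),
      amp_b = g(config$amp_b))
    d$c <- 1 / d$uopt
    d
  }
  out <- if (is.null(config$seed)) draw() else
    with_local_seed(config$seed, draw())
  class(out) <- c("virtual_cohort", "data.frame")
  out
}

#' True condition-specific energetics of a virtual eel
#'
#' The noise-free generating values for one eel under a given added drag and
#' attachment site: drag inflates the minimum cost of transport through the
#' standard metabolic rate (leaving Uopt untouched below 0.2 N, where it
#' drops by `uopt_large_ratio`), and site B adds fixed percentage-point
#' penalties on both endpoints. This is the ground truth every generator
#' encodes and every recovery test compares against.
#'
#' @param eel one row of a [generate_cohort()] data frame.
#' @param drag added drag (N) at the reference speed.
#' @param site attachment site `"A"` or `"B"`.
#' @param config the [cohort_config()].
#' @return a list with `e_u`, `e_c` (true percent effects), `smr_eff`,
#'   `c_eff`, `uopt_eff`, `cotmin_eff`, `ucrit_true`.
#' @export
condition_energetics <- function(eel, drag, site, config = cohort_config()) {
  effective_energetics(eel, drag, site, config)
}

# True (noise-free) condition-specific energetics for one eel.
# Drag inflates COTmin via SMR; Uopt drops only at >= 0.2 N. Site B adds
# fixed percentage-point penalties on both endpoints.
effective_energetics <- function(eel, drag, site, config) {
  e_u <- config$impair_ucrit[1] * drag + config$impair_ucrit[2] * drag^2 +
    if (site == "B") config$site_ucrit_increment else 0
  e_c <- config$impair_cotmin[1] * drag + config$impair_cotmin[2] * drag^2 +
    if (site == "B") config$site_cotmin_increment else 0
  c_base <- 1 / eel$uopt
  cotmin_base <- eel$smr * c_base * exp(1) / 3.6
  uopt_eff <- if (drag >= 0.2) eel$uopt * config$uopt_large_ratio else
    eel$uopt
  c_eff <- 1 / uopt_eff
  cotmin_eff <- cotmin_base * (1 + e_c / 100)
  smr_eff <- 3.6 * cotmin_eff / (c_eff * exp(1))
  list(e_u = e_u, e_c = e_c, smr_eff = smr_eff, c_eff = c_eff,
       uopt_eff = uopt_eff, cotmin_eff = cotmin_eff,
       ucrit_true = eel$ucrit_baseline * (1 - e_u / 100))
}

#' Simulate O2-decline traces for one eel at a series of speeds
#'
#' Each trace is a linear oxygen decline over `duration_h` hours whose slope
#' encodes the eel's true uptake `MO2(U) = SMR_eff * exp(c_eff U)` under the
#' given drag and attachment site, perturbed by multiplicative per-speed MO2
#' noise (`mo2_cv`) and additive per-sample O2 noise (`o2_sd`). Speeds the
#' eel could not sustain (above its condition-specific critical speed) are
#' dropped, as happens in a real protocol.
#'
#' @param eel one row of a [generate_cohort()] data frame.
#' @param speeds tunnel speeds (m s^-1); default 0.3-0.9 in 0.1 steps.
#' @param drag added drag (N) at the reference speed.
#' @param site attachment site `"A"` or `"B"`.
#' @param config the [cohort_config()].
#' @param duration_h trace length (h).
#' @param n_samples samples per trace.
#' @return a list of [o2_trace()] objects, one per retained speed, with the
#'   true MO2 attached as attribute `"true_mo2"`.
#' @export
generate_o2_traces <- function(eel, speeds = seq(0.3, 0.9, 0.1), drag = 0,
                               site = "A", config = cohort_config(),
                               duration_h = 0.5, n_samples = 31) {
  eff <- effective_energetics(eel, drag, site, config)
  speeds <- sustainable_speeds(speeds, eff$ucrit_true)
  sdlog <- sqrt(log(1 + config$mo2_cv^2))
  tt <- seq(0, duration_h, length.out = n_samples)
  veff <- config$chamber_volume - eel$body_mass
  lapply(speeds, function(u) {
    true_mo2 <- eff$smr_eff * exp(eff$c_eff * u)
    mo2 <- true_mo2 * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    slope <- -mo2 * eel$body_mass / veff
    o2 <- config$o2_start + slope * tt +
      stats::rnorm(n_samples, 0, config$o2_sd)
    tr <- o2_trace(tt, o2, config$chamber_volume, eel$body_mass, u)
    attr(tr, "true_mo2") <- true_mo2
    tr
  })
}

#' Simulate a critical-swimming-speed step log for one eel
#'
#' The eel's true condition-specific Ucrit (baseline reduced by the drag and
#' site impairment) is jittered by a lognormal individual response
#' (`effect_sd`) and decomposed into a stepwise fatigue log: every step
#' below the realized Ucrit is completed for the full interval and the
#' fatigue step is held for the proportional remainder, so the Brett formula
#' recovers the realized value exactly.
#'
#' @inheritParams generate_o2_traces
#' @param protocol a [ucrit_protocol()].
#' @return a data frame with columns `step_speed_m_s`, `completed_min`, and
#'   the realized Ucrit as attribute `"true_ucrit"`.
#' @export
generate_ucrit_log <- function(eel, drag = 0, site = "A",
                               config = cohort_config(),
                               protocol = ucrit_protocol()) {
  eff <- effective_energetics(eel, drag, site, config)
  sdl <- config$effect_sd
  u <- eff$ucrit_true * if (sdl > 0) stats::rlnorm(1, -sdl^2 / 2, sdl) else 1
  u <- max(u, protocol$start_speed / 2)  # pathological cohorts still fatigue
  du <- protocol$speed_increment
  if (u < protocol$start_speed) {
    # fatigued during the first step
    steps <- data.frame(step_speed_m_s = protocol$start_speed,
                        completed_min = protocol$interval *
                          u / protocol$start_speed)
  } else {
    n_done <- floor((u - protocol$start_speed) / du) + 1
    done_speeds <- protocol$start_speed + du * (seq_len(n_done) - 1)
    u_i <- done_speeds[n_done]
    t_i <- protocol$interval * (u - u_i) / du
    steps <- data.frame(
      step_speed_m_s = c(done_speeds, u_i + du),
      completed_min = c(rep(protocol$interval, n_done), t_i))
  }
  attr(steps, "true_ucrit") <- u
  steps
}

# Speeds a fish can hold during the (shorter, less demanding) measurement
# steps: everything below its sustained critical speed, but never fewer than
# the three lowest protocol speeds, so per-condition model fits stay defined.
sustainable_speeds <- function(speeds, ucrit_true) {
  speeds <- sort(speeds)
  keep <- speeds <= ucrit_true + 1e-9
  if (sum(keep) < 3) keep <- seq_along(speeds) <= 3
  speeds[keep]
}

# Table of condition-mean kinematic coefficients by (drag, site); values are
# the published group means. An eel's coefficients in a condition are the
# condition mean plus its own control deviation.
kinematic_condition_means <- function(drag, site) {
  if (drag >= 0.2)      c(f_i = 0.48, f_s = 5.98, w_i = 0.35, w_s = 2.03)
  else if (drag >= 0.1 && site == "B")
                        c(f_i = 0.68, f_s = 4.98, w_i = 0.45, w_s = 1.65)
  else if (drag >= 0.1) c(f_i = 0.52, f_s = 2.45, w_i = 0.24, w_s = 1.12)
  else if (drag > 0)    c(f_i = 1.32, f_s = 2.09, w_i = 0.24, w_s = 1.05)
  else                  c(f_i = 1.26, f_s = 2.15, w_i = 0.23, w_s = 1.05)
}

#' Simulate landmark trajectories for one eel at a series of speeds
#'
#' Builds a rearward-travelling lateral wave
#' `y(x, t) = A(x)/2 * sin(2 pi f (t - x / W))` sampled at the three
#' digitized landmarks (site A at 0.125 bl, site B at 0.35 bl, tail tip at
#' 1 bl), with tail-beat frequency and wave speed taken from the
#' condition-specific linear speed regressions and Gaussian digitization
#' noise added to every frame. Tagged conditions shift the regression
#' coefficients the way tagged groups do (steeper f and W slopes under
#' drag, more so at site B); amplitudes are insensitive to tagging.
#'
#' @inheritParams generate_o2_traces
#' @param duration_s track length per speed (s).
#' @param frame_rate sampling rate (Hz).
#' @return a list, one element per speed, each holding `speed` and
#'   [landmark_track()] objects `site_a`, `site_b`, `tail`, plus the true
#'   `f` and `w` as attributes of the element.
#' @export
generate_kinematics <- function(eel, speeds = seq(0.3, 0.9, 0.1), drag = 0,
                                site = "A", config = cohort_config(),
                                duration_s = 20, frame_rate = 30) {
  cond <- kinematic_condition_means(drag, site)
  ctrl <- kinematic_condition_means(0, "A")
  f_i <- cond["f_i"] + (eel$f_intercept - ctrl["f_i"])
  f_s <- cond["f_s"] + (eel$f_slope - ctrl["f_s"])
  w_i <- cond["w_i"] + (eel$w_intercept - ctrl["w_i"])
  w_s <- cond["w_s"] + (eel$w_slope - ctrl["w_s"])
  bl <- eel$body_length
  x_pos <- c(site_a = 0.125, site_b = 0.35, tail = 1) * bl
  amp_m <- c(site_a = eel$amp_a, site_b = eel$amp_b, tail = eel$amp_tail) / 100
  tt <- seq(0, duration_s - 1 / frame_rate, by = 1 / frame_rate)
  eff <- effective_energetics(eel, drag, site, config)
  speeds <- sustainable_speeds(speeds, eff$ucrit_true)
  lapply(speeds, function(u) {
    f <- max(f_i + f_s * u, 0.2)
    w <- max(w_i + w_s * u, 0.05)
    tracks <- lapply(names(x_pos), function(s) {
      y <- amp_m[[s]] / 2 * sin(2 * pi * f * (tt - x_pos[[s]] / w)) +
        stats::rnorm(length(tt), 0, config$kinematic_sd)
      landmark_track(tt, y, frame_rate = frame_rate, swim_speed = u)
    })
    names(tracks) <- names(x_pos)
    out <- c(list(speed = u), tracks)
    attr(out, "true_f") <- f
    attr(out, "true_w") <- w
    out
  })
}

#' Default swim-trial conditions
#'
#' The seven-trial layout of a full tag-effect study: two untagged controls,
#' a support-device-only trial, three dummy sizes at site A, and the
#' intermediate dummy at site B.
#'
#' @return a data frame with columns `condition`, `drag`, `site`.
#' @export
default_conditions <- function() {
  data.frame(
    condition = c("control1", "support_B", "small_A", "intermediate_A",
                  "intermediate_B", "large_A", "control2"),
    drag = c(0, 0, 0.05, 0.1, 0.1, 0.2, 0),
    site = c("A", "A", "A", "A", "B", "A", "A"),
    stringsAsFactors = FALSE)
}

#' Simulate a complete virtual swim-trial study
#'
#' Draws a cohort and, for every eel x condition, generates O2 traces, a
#' Ucrit step log and (optionally) landmark trajectories, together with a
#' truth table of the generating values. All randomness flows through a
#' single generator seeded from `config$seed`, so the bundle is reproducible.
#' When `out_dir` is given the bundle is also written as the standard CSV
#' schemas (`traces.csv`, `steps.csv`, `landmarks.csv`, `truth.csv`).
#'
#' @param config a [cohort_config()].
#' @param conditions a data frame like [default_conditions()].
#' @param kinematics also simulate landmark tracks (slower; default TRUE).
#' @param kinematic_duration_s track length per speed (s).
#' @param out_dir optional directory to write the CSV bundle to.
#' @return a list with `cohort`, `traces` (data frame), `steps` (data
#'   frame), `landmarks` (data frame or NULL), `truth` (data frame),
#'   `config`.
#' @export
simulate_swim_study <- function(config = cohort_config(),
                                conditions = default_conditions(),
                                kinematics = TRUE,
                                kinematic_duration_s = 20,
                                out_dir = NULL) {
  run <- function() {
    cohort <- generate_cohort(structure(utils::modifyList(unclass(config),
                                                   list(seed = NULL)),
                              class = "cohort_config"))
    traces <- list(); steps <- list(); lands <- list(); truth <- list()
    for (i in seq_len(nrow(cohort))) {
      eel <- cohort[i, ]
      for (j in seq_len(nrow(conditions))) {
        cnd <- conditions[j, ]
        eff <- effective_energetics(eel, cnd$drag, cnd$site, config)
        trs <- generate_o2_traces(eel, drag = cnd$drag, site = cnd$site,
                                  config = config)
        traces[[length(traces) + 1]] <- do.call(rbind, lapply(trs, function(tr)
          data.frame(eel_id = eel$eel_id, condition = cnd$condition,
                     speed_m_s = tr$tunnel_speed, time_h = tr$time_h,
                     o2_mg_L = tr$o2_mg_l)))
        lg <- generate_ucrit_log(eel, drag = cnd$drag, site = cnd$site,
                                 config = config)
        steps[[length(steps) + 1]] <-
          data.frame(eel_id = eel$eel_id, condition = cnd$condition,
                     step_speed_m_s = lg$step_speed_m_s,
                     completed_min = lg$completed_min)
        if (kinematics) {
          kin <- generate_kinematics(eel, drag = cnd$drag, site = cnd$site,
                                     config = config,
                                     duration_s = kinematic_duration_s)
          lands[[length(lands) + 1]] <- do.call(rbind, lapply(kin, function(k)
            do.call(rbind, lapply(c("site_a", "site_b", "tail"), function(s)
              data.frame(eel_id = eel$eel_id, condition = cnd$condition,
                         speed_m_s = k$speed, site = s,
                         time_s = k[[s]]$time_s,
                         lateral_m = k[[s]]$lateral_m)))))
        }
        truth[[length(truth) + 1]] <-
          data.frame(eel_id = eel$eel_id, condition = cnd$condition,
                     drag = cnd$drag, site = cnd$site,
                     smr_true = eff$smr_eff, c_true = eff$c_eff,
                     uopt_true = eff$uopt_eff, cotmin_true = eff$cotmin_eff,
                     ucrit_true = attr(lg, "true_ucrit"),
                     body_mass = eel$body_mass,
                     body_length = eel$body_length,
                     fish_area = eel$fish_area)
      }
    }
    list(cohort = cohort,
         traces = do.call(rbind, traces),
         steps = do.call(rbind, steps),
         landmarks = if (kinematics) do.call(rbind, lands) else NULL,
         truth = do.call(rbind, truth),
         config = config)
  }
  bundle <- if (is.null(config$seed)) run() else
    with_local_seed(config$seed, run())
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(bundle$traces, file.path(out_dir, "traces.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$steps, file.path(out_dir, "steps.csv"),
                     row.names = FALSE)
    if (!is.null(bundle$landmarks))
      utils::write.csv(bundle$landmarks, file.path(out_dir, "landmarks.csv"),
                       row.names = FALSE)
    utils::write.csv(bundle$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  bundle
}
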