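#' CSV schemas used by the pipeline
#'
#' Column names and types of the delimited-text formats the package reads
#' and writes: O2 traces, Ucrit step logs, digitized landmark tracks, drag
#' calibrations and per-individual effect tables. All files use dot decimal
#' separators, UTF-8, and speeds in m s^-1.
#'
#' @return a named list of schema descriptions (`columns`, `types`, `key`).
#' @export
swim_schemas <- function() {
  list(
    traces = list(
      columns = c("eel_id", "condition", "speed_m_s", "time_h", "o2_mg_L"),
      types = c("character", "character", "numeric", "numeric", "numeric"),
      key = NULL),
    steps = list(
      columns = c("eel_id", "condition", "step_speed_m_s", "completed_min"),
      types = c("character", "character", "numeric", "numeric"),
      key = c("eel_id", "condition", "step_speed_m_s")),
    landmarks = list(
      columns = c("eel_id", "condition", "speed_m_s", "site", "time_s",
                  "lateral_m"),
      types = c("character", "character", "numeric", "character", "numeric",
                "numeric"),
      key = NULL),
    drag_calibration = list(
      columns = c("speed_m_s", "force_N", "replicate", "dummy_label"),
      types = c("numeric", "numeric", "character", "character"),
      key = NULL),
    effects = list(
      columns = c("eel_id", "drag_N", "red_pct_ucrit", "inc_pct_cotmin"),
      types = c("character", "numeric", "numeric", "numeric"),
      key = c("eel_id", "drag_N")))
}

#' Read a validated pipeline table
#'
#' Reads a CSV against one of the [swim_schemas()]: missing columns are
#' reported by name, non-numeric cells in numeric columns are reported by
#' row, and duplicate key combinations are rejected.
#'
#' @param path path to a CSV file.
#' @param schema schema name, one of `names(swim_schemas())`.
#' @return a data frame with typed columns, in file order.
#' @export
read_swim_table <- function(path, schema) {
  schemas <- swim_schemas()
  if (!schema %in% names(schemas))
    stop("unknown schema '", schema, "'; available: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  sc <- schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(sc$columns, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[sc$columns]
  for (i in seq_along(sc$columns)) {
    if (sc$types[i] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[i]]))
      bad <- which(is.na(v) & !(df[[i]] %in% c("", "NA")))
      if (length(bad))
        stop("non-numeric value in column `", sc$columns[i], "`, row ",
             bad[1], " of ", path, call. = FALSE)
      df[[i]] <- v
    }
  }
  if (!is.null(sc$key)) {
    dup <- duplicated(df[sc$key])
    if (any(dup))
      stop("duplicate (", paste(sc$key, collapse = ", "), ") key at row ",
           which(dup)[1], " of ", path, call. = FALSE)
  }
  df
}

#' Write a pipeline table
#'
#' @param df data frame matching the schema.
#' @param path output path.
#' @param schema schema name; when given, columns are checked and ordered.
#' @return `path`, invisibly.
#' @export
write_swim_table <- function(df, path, schema = NULL) {
  if (!is.null(schema)) {
    sc <- swim_schemas()[[schema]]
    missing <- setdiff(sc$columns, names(df))
    if (length(missing))
      stop("data frame missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    df <- df[sc$columns]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every tunable the pipeline stages use: fluid environment, Ucrit
#' protocol, MO2 acceptance thresholds, the solid-blocking context, the
#' condition table mapping condition labels to drags and sites, attachment
#' site increments and the RNG seed.
#'
#' @param env a [fluid_env()].
#' @param protocol a [ucrit_protocol()].
#' @param min_r2 minimum O2-slope r-squared for MO2 acceptance.
#' @param alpha slope significance level.
#' @param blocking a [blocking_context()], or `NULL` to skip the speed
#'   correction (it is of order a few percent).
#' @param conditions condition table, as [default_conditions()].
#' @param site_ucrit_increment,site_cotmin_increment site-B percentage-point
#'   penalties used when evaluating tags.
#' @param seed integer seed for any randomized stage (segment selection).
#' @return an object of class `run_config`.
#' @export
run_config <- function(env = fluid_env(), protocol = ucrit_protocol(),
                       min_r2 = 0.9, alpha = 0.05, blocking = NULL,
                       conditions = default_conditions(),
                       site_ucrit_increment = 15,
                       site_cotmin_increment = 63, seed = 1L) {
  structure(list(env = env, protocol = protocol, min_r2 = min_r2,
                 alpha = alpha, blocking = blocking,
                 conditions = conditions,
                 site_ucrit_increment = site_ucrit_increment,
                 site_cotmin_increment = site_cotmin_increment, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts a flat YAML file with any of the keys `density`,
#' `drag_coefficient`, `reference_speed`, `speed_increment`, `interval`,
#' `start_speed`, `min_r2`, `alpha`, `fish_area`, `tunnel_area`, `tau`,
#' `lam`, `apply_blocking`, `site_ucrit_increment`, `site_cotmin_increment`,
#' `seed`. Unknown keys are rejected with a clear message.
#'
#' @param path path to a YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("density", "drag_coefficient", "reference_speed",
             "speed_increment", "interval", "start_speed", "min_r2", "alpha",
             "fish_area", "tunnel_area", "tau", "lam", "apply_blocking",
             "site_ucrit_increment", "site_cotmin_increment", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  g <- function(nm, default) if (!is.null(y[[nm]])) y[[nm]] else default
  env <- fluid_env(g("density", 1020), g("drag_coefficient", 0.45),
                   g("reference_speed", 0.65))
  protocol <- ucrit_protocol(g("speed_increment", 0.1), g("interval", 20),
                             g("start_speed", 0.3))
  blocking <- if (isTRUE(y$apply_blocking))
    blocking_context(g("fish_area", 150.5), g("tunnel_area", 610),
                     g("tau", 0.8), g("lam", 0.5)) else NULL
  run_config(env = env, protocol = protocol, min_r2 = g("min_r2", 0.9),
             alpha = g("alpha", 0.05), blocking = blocking,
             site_ucrit_increment = g("site_ucrit_increment", 15),
             site_cotmin_increment = g("site_cotmin_increment", 63),
             seed = g("seed", 1L))
}

#' Run the full tag-effect analysis pipeline
#'
#' Orchestrates the stages over a directory of standard CSV inputs
#' (`traces.csv`, `steps.csv`, optionally `landmarks.csv`): per eel x
#' condition it extracts oxygen-uptake samples from the O2 traces (logging
#' every rejection), fits the exponential metabolic model and derives SMR,
#' Uopt and COTmin; reduces the step logs to Brett critical swimming speeds;
#' summarises kinematics (tail-beat frequency, amplitudes, wave speed,
#' Strouhal number) per speed and fits their speed regressions; and, where
#' at least two positive drag levels are present, computes per-individual
#' percent effects against the control condition and fits the through-origin
#' quadratic impairment models. Stages whose inputs are absent are skipped
#' with an explicit notice, never silently.
#'
#' @param config a [run_config()].
#' @param data_dir directory containing the input CSVs.
#' @param out_dir optional directory for the JSON + CSV report.
#' @param control_condition label of the untagged baseline condition.
#' @return a list of class `dragtag_report` with components `energetics`,
#'   `ucrit`, `kinematics`, `effects`, `impairment`, `log`, `skipped`.
#' @export
run_pipeline <- function(config = run_config(), data_dir, out_dir = NULL,
                         control_condition = "control1") {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  skipped <- character()
  paths <- file.path(data_dir, c(traces = "traces.csv", steps = "steps.csv",
                                 landmarks = "landmarks.csv"))
  names(paths) <- c("traces", "steps", "landmarks")
  if (!file.exists(paths["traces"]) && !file.exists(paths["steps"]))
    stop("no pipeline inputs in ", data_dir,
         ": need traces.csv and/or steps.csv", call. = FALSE)

  eps <- if (is.null(config$blocking)) 0 else
    fractional_error(config$blocking)

  # optional per-eel metadata sidecar (body mass and length); the synthetic
  # bundle writes these in truth.csv, field data can supply the same columns
  meta <- NULL
  for (cand in c("metadata.csv", "truth.csv")) {
    p <- file.path(data_dir, cand)
    if (file.exists(p)) {
      m <- utils::read.csv(p, stringsAsFactors = FALSE)
      if ("eel_id" %in% names(m)) meta <- m[!duplicated(m$eel_id), ]
      break
    }
  }
  eel_meta <- function(id, col, default) {
    if (is.null(meta) || !col %in% names(meta)) return(default)
    hit <- match(id, meta$eel_id)
    if (is.na(hit)) default else meta[[col]][hit]
  }

  ## -- energetics -------------------------------------------------------
  energetics <- NULL
  if (file.exists(paths["traces"])) {
    tr <- read_swim_table(paths["traces"], "traces")
    groups <- unique(tr[c("eel_id", "condition")])
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      gi <- groups[i, ]
      sub <- tr[tr$eel_id == gi$eel_id & tr$condition == gi$condition, ]
      mass <- eel_meta(gi$eel_id, "body_mass", 0.65)
      speeds <- sort(unique(sub$speed_m_s))
      samples <- lapply(speeds, function(u) {
        s2 <- sub[sub$speed_m_s == u, ]
        trc <- o2_trace(s2$time_h, s2$o2_mg_L, 127, mass, u)
        mo2_from_trace(trc, min_r2 = config$min_r2, alpha = config$alpha)
      })
      acc <- vapply(samples, `[[`, TRUE, "accepted")
      for (k in which(!acc))
        note("rejected MO2 sample: ", gi$eel_id, " ", gi$condition,
             " at ", speeds[k], " m s^-1 (r2 = ",
             sprintf("%.3f", samples[[k]]$r2), ", p = ",
             sprintf("%.3g", samples[[k]]$p_value), ")")
      if (sum(acc) < 3) {
        note("skipped metabolic fit (",
             sum(acc), " accepted samples): ", gi$eel_id, " ", gi$condition)
        return(NULL)
      }
      u_acc <- (1 + eps) * speeds[acc]
      mo2_acc <- vapply(samples[acc], `[[`, 0, "mo2")
      m <- tryCatch(fit_metabolic_model(u_acc, mo2_acc),
                    error = function(e) NULL)
      if (is.null(m)) {
        note("skipped metabolic fit (non-convergence): ", gi$eel_id, " ",
             gi$condition)
        return(NULL)
      }
      if (m$c <= 0) {
        # MO2 not rising with speed: Uopt/COTmin undefined for this fit
        note("skipped energetic endpoints (non-positive exponent): ",
             gi$eel_id, " ", gi$condition)
        return(NULL)
      }
      data.frame(eel_id = gi$eel_id, condition = gi$condition,
                 smr = m$smr, c = m$c, fit_r2 = m$fit_r2,
                 uopt = uopt(m), cotmin = cot_min(m),
                 n_accepted = sum(acc))
    })
    energetics <- do.call(rbind, rows)
  } else {
    skipped <- c(skipped, "energetics: traces.csv absent")
  }

  ## -- critical swimming speed -----------------------------------------
  ucrit_tab <- NULL
  if (file.exists(paths["steps"])) {
    st <- read_swim_table(paths["steps"], "steps")
    groups <- unique(st[c("eel_id", "condition")])
    ucrit_tab <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      gi <- groups[i, ]
      sub <- st[st$eel_id == gi$eel_id & st$condition == gi$condition, ]
      res <- ucrit_from_log(sub$step_speed_m_s, sub$completed_min,
                            protocol = config$protocol,
                            blocking = config$blocking)
      data.frame(eel_id = gi$eel_id, condition = gi$condition,
                 u_crit = res$u_crit,
                 last_completed_speed = res$last_completed_speed,
                 fatigue_time = res$fatigue_time)
    }))
  } else {
    skipped <- c(skipped, "ucrit: steps.csv absent")
  }

  ## -- kinematics ------------------------------------------------------
  kin_summary <- NULL
  kin_fits <- NULL
  if (file.exists(paths["landmarks"])) {
    lm_tab <- read_swim_table(paths["landmarks"], "landmarks")
    groups <- unique(lm_tab[c("eel_id", "condition", "speed_m_s")])
    kin_summary <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      gi <- groups[i, ]
      sub <- lm_tab[lm_tab$eel_id == gi$eel_id &
                      lm_tab$condition == gi$condition &
                      lm_tab$speed_m_s == gi$speed_m_s, ]
      mk <- function(s) {
        s2 <- sub[sub$site == s, ]
        if (!nrow(s2)) return(NULL)
        landmark_track(s2$time_s, s2$lateral_m,
                       frame_rate = 1 / stats::median(diff(s2$time_s)),
                       swim_speed = gi$speed_m_s)
      }
      tail_t <- mk("tail"); a_t <- mk("site_a"); b_t <- mk("site_b")
      if (is.null(tail_t)) return(NULL)
      bl <- eel_meta(gi$eel_id, "body_length", 0.657)
      f <- tryCatch(tailbeat_frequency(tail_t), error = function(e) NA_real_)
      a_cm <- lateral_amplitude(tail_t)
      w <- if (!is.null(a_t) && !is.null(b_t))
        tryCatch(wave_speed(a_t, b_t, 0.225 * bl), error = function(e) NA_real_)
      else NA_real_
      u_corr <- (1 + eps) * gi$speed_m_s
      data.frame(eel_id = gi$eel_id, condition = gi$condition,
                 speed_m_s = u_corr, f = f, a = a_cm,
                 a_A = if (is.null(a_t)) NA_real_ else lateral_amplitude(a_t),
                 a_B = if (is.null(b_t)) NA_real_ else lateral_amplitude(b_t),
                 W = w, st = strouhal(a_cm / 100, f, u_corr))
    }))
    fit_groups <- unique(kin_summary[c("eel_id", "condition")])
    kin_fits <- do.call(rbind, lapply(seq_len(nrow(fit_groups)), function(i) {
      gi <- fit_groups[i, ]
      sub <- kin_summary[kin_summary$eel_id == gi$eel_id &
                           kin_summary$condition == gi$condition, ]
      sub <- sub[is.finite(sub$f) & is.finite(sub$W), ]
      if (length(unique(sub$speed_m_s)) < 3) {
        note("skipped kinematic fits (<3 speeds): ", gi$eel_id, " ",
             gi$condition)
        return(NULL)
      }
      ff <- fit_kinematic(sub$speed_m_s, sub$f, "f")
      wf <- fit_kinematic(sub$speed_m_s, sub$W, "W")
      data.frame(eel_id = gi$eel_id, condition = gi$condition,
                 f_intercept = ff$intercept, f_slope = ff$slope,
                 f_r2 = ff$r2, w_intercept = wf$intercept,
                 w_slope = wf$slope, w_r2 = wf$r2)
    }))
  } else {
    skipped <- c(skipped, "kinematics: landmarks.csv absent")
  }

  ## -- impairment ------------------------------------------------------
  effects <- NULL
  impairment <- NULL
  cond_tab <- config$conditions
  if (!is.null(energetics) && !is.null(ucrit_tab) &&
      control_condition %in% energetics$condition) {
    endpoints <- merge(
      ucrit_tab[c("eel_id", "condition", "u_crit")],
      energetics[c("eel_id", "condition", "cotmin")],
      by = c("eel_id", "condition"))
    names(endpoints)[names(endpoints) == "u_crit"] <- "ucrit"
    endpoints <- merge(endpoints, cond_tab, by = "condition")
    ctrl <- endpoints[endpoints$condition == control_condition,
                      c("eel_id", "ucrit", "cotmin")]
    trt <- endpoints[endpoints$drag > 0 & endpoints$site == "A", ]
    if (nrow(ctrl) && length(unique(trt$drag)) >= 2) {
      effects <- percent_effects(ctrl, trt[c("eel_id", "drag", "ucrit",
                                             "cotmin")])
      impairment <- list(
        ucrit = fit_impairment(effects, "ucrit"),
        cotmin = fit_impairment(effects, "cotmin"))
    } else {
      skipped <- c(skipped,
                   "impairment: need a control and >= 2 site-A drag levels")
    }
  } else if (is.null(energetics) || is.null(ucrit_tab)) {
    skipped <- c(skipped, "impairment: upstream energetics or ucrit missing")
  }

  report <- structure(
    list(energetics = energetics, ucrit = ucrit_tab,
         kinematics = list(summary = kin_summary, fits = kin_fits),
         effects = effects, impairment = impairment,
         blocking_fraction = eps, log = log, skipped = skipped,
         control_condition = control_condition),
    class = "dragtag_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(energetics))
      utils::write.csv(energetics, file.path(out_dir, "energetics.csv"),
                       row.names = FALSE)
    if (!is.null(ucrit_tab))
      utils::write.csv(ucrit_tab, file.path(out_dir, "ucrit.csv"),
                       row.names = FALSE)
    if (!is.null(kin_fits))
      utils::write.csv(kin_fits, file.path(out_dir, "kinematic_fits.csv"),
                       row.names = FALSE)
    if (!is.null(effects))
      utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                       row.names = FALSE)
    json <- list(
      condition_means = if (!is.null(energetics))
        stats::aggregate(cbind(smr, uopt, cotmin) ~ condition,
                         data = energetics, FUN = mean) else NULL,
      ucrit_means = if (!is.null(ucrit_tab))
        stats::aggregate(u_crit ~ condition, data = ucrit_tab, FUN = mean)
      else NULL,
      impairment = if (!is.null(impairment)) list(
        ucrit = as.list(coef(impairment$ucrit)),
        cotmin = as.list(coef(impairment$cotmin))) else NULL,
      blocking_fraction = eps,
      skipped = skipped, log = log)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.dragtag_report <- function(x, ...) {
  cat("Tag-effect pipeline report\n")
  if (!is.null(x$energetics)) {
    cm <- stats::aggregate(cbind(smr, uopt, cotmin) ~ condition,
                           data = x$energetics, FUN = mean)
    cat("\nCondition means (SMR mgO2 kg^-1 h^-1, Uopt m s^-1, COTmin mgO2 kg^-1 km^-1):\n")
    print(cm, row.names = FALSE)
  }
  if (!is.null(x$ucrit)) {
    um <- stats::aggregate(u_crit ~ condition, data = x$ucrit, FUN = mean)
    cat("\nMean Ucrit (m s^-1):\n")
    print(um, row.names = FALSE)
  }
  if (!is.null(x$impairment)) {
    cat("\n")
    print(x$impairment$ucrit)
    print(x$impairment$cotmin)
  }
  if (length(x$skipped))
    cat("\nSkipped stages:\n", paste(" -", x$skipped, collapse = "\n"), "\n")
  cat(sprintf("\n%d filter decisions logged; blocking correction %+.2f%%\n",
              length(x$log), 100 * x$blocking_fraction))
  invisible(x)
}
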