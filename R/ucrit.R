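#' Stepwise critical-swimming-speed protocol
#'
#' Parameters of an incremental fatigue test: tunnel speed rises by
#' `speed_increment` every `interval` minutes, starting at `start_speed`,
#' until the fish fatigues (refuses to swim and is flushed against the
#' downstream grid).
#'
#' @param speed_increment speed step size (m s^-1), default 0.1.
#' @param interval step duration (min), default 20.
#' @param start_speed speed of the first step (m s^-1), default 0.3.
#' @return an object of class `ucrit_protocol`.
#' @export
ucrit_protocol <- function(speed_increment = 0.1, interval = 20,
                           start_speed = 0.3) {
  if (speed_increment <= 0) stop("`speed_increment` must be positive",
                                 call. = FALSE)
  if (interval <= 0) stop("`interval` must be positive", call. = FALSE)
  if (start_speed <= 0) stop("`start_speed` must be positive", call. = FALSE)
  structure(list(speed_increment = speed_increment, interval = interval,
                 start_speed = start_speed),
            class = "ucrit_protocol")
}

#' Brett critical swimming speed
#'
#' `Ucrit = U_i + dU * (T_i / dT)`, where `U_i` is the highest speed the fish
#' maintained for an entire interval, `T_i` is how long it endured the final
#' (fatigue) step, and `dU`, `dT` are the protocol increments. If the fish
#' fatigues during the very first step, pass `last_completed_speed = 0`: the
#' increment is then taken as the start speed, so `Ucrit = start_speed *
#' T_i / dT`.
#'
#' @param last_completed_speed `U_i` (m s^-1); 0 if the fish never completed
#'   a step.
#' @param fatigue_time `T_i` (min), in `[0, interval]`.
#' @param protocol a [ucrit_protocol()].
#' @param blocking optional [blocking_context()]; when supplied the result is
#'   corrected for the solid blocking effect (the correction is a constant
#'   factor, so it commutes with the Brett formula).
#' @return an object of class `ucrit_result` with fields `u_crit`,
#'   `u_crit_raw`, `last_completed_speed`, `fatigue_time`.
#' @examples
#' compute_ucrit(0.8, 10)  # 0.85 m s^-1
#' @export
compute_ucrit <- function(last_completed_speed, fatigue_time,
                          protocol = ucrit_protocol(), blocking = NULL) {
  if (last_completed_speed < 0)
    stop("`last_completed_speed` must be non-negative", call. = FALSE)
  if (fatigue_time < 0)
    stop("`fatigue_time` must be non-negative", call. = FALSE)
  if (fatigue_time > protocol$interval)
    stop("`fatigue_time` exceeds the step interval: that step was completed; ",
         "advance `last_completed_speed` instead", call. = FALSE)
  du <- if (last_completed_speed == 0) protocol$start_speed else
    protocol$speed_increment
  u_raw <- last_completed_speed + du * fatigue_time / protocol$interval
  u <- if (is.null(blocking)) u_raw else correct_speed(u_raw, blocking)
  structure(list(u_crit = u, u_crit_raw = u_raw,
                 last_completed_speed = last_completed_speed,
                 fatigue_time = fatigue_time, protocol = protocol,
                 corrected = !is.null(blocking)),
            class = "ucrit_result")
}

#' @export
print.ucrit_result <- function(x, ...) {
  cat(sprintf("Ucrit = %.3f m s^-1%s (U_i = %.2f, T_i = %.1f min of %g)\n",
              x$u_crit,
              if (x$corrected) " (blocking-corrected)" else "",
              x$last_completed_speed, x$fatigue_time, x$protocol$interval))
  invisible(x)
}

#' Critical swimming speed from a step log
#'
#' Reduces a fatigue-test log (one row per speed step with the minutes the
#' fish endured it) to `U_i` and `T_i` and applies the Brett formula. A step
#' counts as completed when its duration reached the protocol interval (to
#' within `tol` minutes).
#'
#' @param step_speed speeds of the steps attempted (m s^-1), increasing.
#' @param completed_min minutes endured at each step.
#' @param protocol a [ucrit_protocol()].
#' @param blocking optional [blocking_context()].
#' @param tol completion tolerance (min).
#' @return a `ucrit_result`.
#' @export
ucrit_from_log <- function(step_speed, completed_min,
                           protocol = ucrit_protocol(), blocking = NULL,
                           tol = 1e-8) {
  if (length(step_speed) != length(completed_min) || length(step_speed) == 0)
    stop("step log must have matching, non-empty speed and duration columns",
         call. = FALSE)
  o <- order(step_speed)
  step_speed <- step_speed[o]; completed_min <- completed_min[o]
  done <- completed_min >= protocol$interval - tol
  if (all(done)) # fish never fatigued: Ucrit is right-censored at the top step
    return(compute_ucrit(step_speed[length(step_speed)], protocol$interval,
                         protocol, blocking))
  i_fail <- which(!done)[1]
  if (i_fail < length(step_speed))
    stop("step log inconsistent: steps recorded after the fatigue step",
         call. = FALSE)
  u_i <- if (i_fail == 1) 0 else step_speed[i_fail - 1]
  compute_ucrit(u_i, completed_min[i_fail], protocol, blocking)
}
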