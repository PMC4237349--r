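#' Randomly select analysis segments from a video recording
#'
#' Divides a recording of `total_duration` seconds into `n_blocks` equal
#' blocks and draws one `segment_length`-second window uniformly at random
#' from the non-overlapping slots of each block. The defaults reproduce the
#' standard sub-sampling of a 20-min recording: three 400-s blocks, each cut
#' into twenty 20-s slots, one slot drawn per block.
#'
#' @param total_duration recording length (s).
#' @param segment_length window length (s); must divide the block length.
#' @param n_blocks number of equal blocks.
#' @param seed optional integer; when given, selection is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a data frame with columns `start`, `end` (s), one row per block.
#' @export
select_segments <- function(total_duration = 1200, segment_length = 20,
                            n_blocks = 3, seed = NULL) {
  block_len <- total_duration / n_blocks
  if (abs(block_len - round(block_len)) > 1e-9 * total_duration)
    stop("`total_duration` must be divisible by `n_blocks`", call. = FALSE)
  if (segment_length > block_len)
    stop("`segment_length` exceeds the block length", call. = FALSE)
  n_slots <- block_len / segment_length
  if (abs(n_slots - round(n_slots)) > 1e-9)
    stop("`segment_length` must divide the block length", call. = FALSE)
  n_slots <- round(n_slots)
  draw <- function() sample.int(n_slots, n_blocks, replace = TRUE)
  slots <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  start <- (seq_len(n_blocks) - 1) * block_len + (slots - 1) * segment_length
  data.frame(start = start, end = start + segment_length)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  expr
}

#' Digitized lateral-position track of one body landmark
#'
#' @param time_s frame times (s), uniformly spaced.
#' @param lateral_m lateral (side-to-side) position of the landmark (m).
#' @param frame_rate video frame rate (Hz); default 30.
#' @param swim_speed tunnel speed during filming (m s^-1).
#' @return an object of class `landmark_track`.
#' @export
landmark_track <- function(time_s, lateral_m, frame_rate = 30,
                           swim_speed = NA_real_) {
  if (length(time_s) != length(lateral_m) || length(time_s) < 2)
    stop("track needs matching time and position vectors (length >= 2)",
         call. = FALSE)
  dt <- diff(time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("`time_s` must be uniformly sampled and increasing", call. = FALSE)
  structure(list(time_s = time_s, lateral_m = lateral_m,
                 frame_rate = frame_rate, swim_speed = swim_speed),
            class = "landmark_track")
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("Landmark track: %d frames at %g Hz (%.1f s) at U = %g m s^-1\n",
              length(x$time_s), x$frame_rate, diff(range(x$time_s)),
              x$swim_speed))
  invisible(x)
}

# Window a track; linear-detrend the lateral signal (removes offset + drift).
window_signal <- function(track, window = NULL) {
  t <- track$time_s; y <- track$lateral_m
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    if (!any(keep)) stop("window contains no samples", call. = FALSE)
    t <- t[keep]; y <- y[keep]
  }
  y <- stats::residuals(stats::lm(y ~ t))
  list(t = t, y = as.numeric(y))
}

#' Tail-beat frequency by cycle counting
#'
#' Counts full oscillation cycles of the mean-centred lateral signal over a
#' window and divides by the window duration. A cycle is a pair of
#' mean-crossings; the signal is linearly detrended first, so slow drift and
#' a constant offset do not bias the count.
#'
#' @param track a [landmark_track()].
#' @param window optional `(start, end)` in seconds; default is the full
#'   track.
#' @return frequency (Hz).
#' @export
tailbeat_frequency <- function(track, window = NULL) {
  w <- window_signal(track, window)
  if (all(abs(w$y) < 1e-10))
    stop("flat signal: no oscillation to count", call. = FALSE)
  s <- sign(w$y)
  s[s == 0] <- 1
  crossings <- sum(diff(s) != 0)
  if (crossings < 2)
    stop("fewer than 2 mean-crossings: frequency undefined", call. = FALSE)
  (crossings / 2) / diff(range(w$t))
}

#' Peak-to-peak lateral amplitude
#'
#' The difference between the two outermost lateral positions of a landmark
#' over a window, reported in cm.
#'
#' @inheritParams tailbeat_frequency
#' @return peak-to-peak amplitude (cm).
#' @export
lateral_amplitude <- function(track, window = NULL) {
  t <- track$time_s; y <- track$lateral_m
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    if (!any(keep)) stop("window contains no samples", call. = FALSE)
    y <- y[keep]
  }
  100 * (max(y) - min(y))
}

#' Body-wave speed from two landmark tracks
#'
#' The propulsive wave travels rearward along the body; its speed is the arc
#' distance between two landmarks divided by the time lag of the lateral
#' oscillation between them. The lag is located at the peak of the
#' cross-correlation of the detrended signals, refined to sub-frame
#' resolution by parabolic interpolation around the peak.
#'
#' @param track_front track of the anterior landmark.
#' @param track_rear track of the posterior landmark (same sampling).
#' @param separation arc distance between the landmarks (m).
#' @param window optional `(start, end)` window (s).
#' @return wave speed (m s^-1). Errors when the correlation peak sits at
#'   (or interpolates to) zero lag, where the speed is undefined.
#' @export
wave_speed <- function(track_front, track_rear, separation, window = NULL) {
  if (separation <= 0) stop("`separation` must be positive", call. = FALSE)
  a <- window_signal(track_front, window)
  b <- window_signal(track_rear, window)
  n <- min(length(a$y), length(b$y))
  ya <- a$y[seq_len(n)]; yb <- b$y[seq_len(n)]
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0)
    stop("flat signal: no oscillation to correlate", call. = FALSE)
  dt <- 1 / track_front$frame_rate
  max_lag <- floor(n / 3)
  cc <- stats::ccf(yb, ya, lag.max = max_lag, plot = FALSE)
  lags <- drop(cc$lag); acfv <- drop(cc$acf)
  k <- which.max(acfv)
  lag_frames <- lags[k]
  # parabolic refinement using the two neighbours of the discrete peak
  if (k > 1 && k < length(acfv)) {
    denom <- acfv[k - 1] - 2 * acfv[k] + acfv[k + 1]
    if (denom < 0)
      lag_frames <- lag_frames + 0.5 * (acfv[k - 1] - acfv[k + 1]) / denom
  }
  lag_s <- lag_frames * dt
  if (abs(lag_s) < dt / 4)
    stop("zero phase lag between landmarks: wave speed undefined",
         call. = FALSE)
  separation / abs(lag_s)
}

#' Strouhal number
#'
#' `St = a f / U` with `a` the peak-to-peak tail-beat amplitude in metres,
#' `f` the tail-beat frequency and `U` the swimming speed. Cruising fish
#' typically fall in 0.2-0.4; higher values indicate kinematic compensation
#' and reduced propulsive efficiency.
#'
#' @param amplitude_m peak-to-peak tail-beat amplitude (m).
#' @param frequency tail-beat frequency (Hz).
#' @param speed swimming speed (m s^-1), strictly positive.
#' @return the dimensionless Strouhal number.
#' @export
strouhal <- function(amplitude_m, frequency, speed) {
  if (any(speed <= 0)) stop("`speed` must be positive", call. = FALSE)
  amplitude_m * frequency / speed
}

#' Linear speed regression of a kinematic variable
#'
#' Tail-beat frequency and body-wave speed both rise linearly with swimming
#' speed; this fits `y = intercept + slope * U` by ordinary least squares.
#'
#' @param speed swimming speeds (m s^-1); at least 3 distinct values.
#' @param value kinematic variable at each speed (e.g. `f` in Hz or `W` in
#'   m s^-1).
#' @param variable optional label carried in the result.
#' @return an object of class `kinematic_fit` with `intercept`, `slope`,
#'   `r2`.
#' @export
fit_kinematic <- function(speed, value, variable = "f") {
  if (length(unique(speed)) < 3)
    stop("need >= 3 distinct speeds", call. = FALSE)
  fit <- stats::lm(value ~ speed)
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 r2 = suppressWarnings(summary(fit))$r.squared,
                 variable = variable,
                 speed = speed, value = value),
            class = "kinematic_fit")
}

#' @export
print.kinematic_fit <- function(x, ...) {
  cat(sprintf("Kinematic fit: %s = %.3f %+.3f U  (r^2 = %.3f, n = %d)\n",
              x$variable, x$intercept, x$slope, x$r2, length(x$speed)))
  invisible(x)
}

#' @export
coef.kinematic_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.kinematic_fit <- function(object, speed = object$speed, ...) {
  object$intercept + object$slope * speed
}
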