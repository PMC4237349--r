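#' Per-individual percent effects of added drag
#'
#' Pairs each individual's control endpoints with its endpoints under a known
#' added drag and expresses the change in percent:
#' reduction of critical swimming speed
#' `red%Ucrit = 100 (Ucrit_ctrl - Ucrit_trt) / Ucrit_ctrl`, and increase of
#' minimum cost of transport
#' `inc%COTmin = 100 (COTmin_trt - COTmin_ctrl) / COTmin_ctrl`.
#'
#' @param control data frame with columns `eel_id`, `ucrit`, `cotmin`
#'   (untagged baseline, one row per individual).
#' @param treated data frame with columns `eel_id`, `drag`, `ucrit`,
#'   `cotmin` (one row per individual x drag level).
#' @return a data frame with columns `eel_id`, `drag`, `red_pct_ucrit`,
#'   `inc_pct_cotmin`.
#' @export
percent_effects <- function(control, treated) {
  need_c <- c("eel_id", "ucrit", "cotmin")
  need_t <- c("eel_id", "drag", "ucrit", "cotmin")
  if (!all(need_c %in% names(control)))
    stop("`control` needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  if (!all(need_t %in% names(treated)))
    stop("`treated` needs columns: ", paste(need_t, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(control$eel_id))
    stop("`control` must have one row per individual", call. = FALSE)
  miss <- setdiff(treated$eel_id, control$eel_id)
  if (length(miss))
    stop("treated individuals missing from control: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  idx <- match(treated$eel_id, control$eel_id)
  if (any(control$ucrit[idx] <= 0) || any(control$cotmin[idx] <= 0))
    stop("control endpoints must be positive", call. = FALSE)
  data.frame(
    eel_id = treated$eel_id,
    drag = treated$drag,
    red_pct_ucrit = 100 * (control$ucrit[idx] - treated$ucrit) /
      control$ucrit[idx],
    inc_pct_cotmin = 100 * (treated$cotmin - control$cotmin[idx]) /
      control$cotmin[idx])
}

#' Fit the through-origin quadratic impairment model
#'
#' Least squares of `E = a F_D + b F_D^2` with no intercept, mapping added
#' drag (N, at the reference speed) to the percent change of an energetic
#' endpoint. The model passes through the origin by construction: zero added
#' drag produces zero effect. By default all individual points are pooled
#' (e.g. 8 individuals x 3 drag levels = 24 points); `pooled = FALSE` first
#' averages effects per drag level.
#'
#' @param effects a data frame as returned by [percent_effects()], with
#'   columns `drag` and the endpoint column.
#' @param endpoint which effect to model: `"ucrit"` (reduction of critical
#'   swimming speed, column `red_pct_ucrit`) or `"cotmin"` (increase of
#'   minimum cost of transport, column `inc_pct_cotmin`).
#' @param pooled fit all individual points (default) or drag-level means.
#' @return an object of class `impairment_fit` with `lin_coeff` (a, % N^-1),
#'   `quad_coeff` (b, % N^-2), standard errors `coeff_se`, `fit_r2`, and the
#'   fitted drag range.
#' @examples
#' fd <- c(0.05, 0.1, 0.2)
#' eff <- data.frame(drag = fd, red_pct_ucrit = 102.8 * fd + 527.7 * fd^2)
#' coef(fit_impairment(eff, "ucrit"))
#' @export
fit_impairment <- function(effects, endpoint = c("ucrit", "cotmin"),
                           pooled = TRUE) {
  endpoint <- match.arg(endpoint)
  col <- switch(endpoint, ucrit = "red_pct_ucrit", cotmin = "inc_pct_cotmin")
  if (!all(c("drag", col) %in% names(effects)))
    stop("`effects` needs columns `drag` and `", col, "`", call. = FALSE)
  drag <- effects$drag
  e <- effects[[col]]
  keep <- is.finite(drag) & is.finite(e) & drag > 0
  drag <- drag[keep]; e <- e[keep]
  if (length(unique(drag)) < 2)
    stop("need effects at >= 2 distinct positive drag levels", call. = FALSE)
  if (!pooled) {
    e <- tapply(e, drag, mean)
    drag <- as.numeric(names(e)); e <- as.numeric(e)
  }
  fit <- stats::lm(e ~ 0 + drag + I(drag^2))
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, 2]
  sst <- sum((e - mean(e))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(endpoint = endpoint,
                 lin_coeff = unname(cf["drag"]),
                 quad_coeff = unname(cf["I(drag^2)"]),
                 coeff_se = c(lin = unname(se["drag"]),
                              quad = unname(se["I(drag^2)"])),
                 fit_r2 = r2, drag_range = c(0, max(drag)),
                 n = length(e), pooled = pooled),
            class = "impairment_fit")
}

#' @export
print.impairment_fit <- function(x, ...) {
  lab <- switch(x$endpoint, ucrit = "reduction %Ucrit",
                cotmin = "increase %COTmin")
  cat(sprintf("Impairment model (%s): E = %.4g F_D %+.4g F_D^2\n",
              lab, x$lin_coeff, x$quad_coeff))
  cat(sprintf("  SE: a %.4g, b %.4g; r^2 = %.3f on %d points (drag <= %g N)\n",
              x$coeff_se["lin"], x$coeff_se["quad"], x$fit_r2, x$n,
              x$drag_range[2]))
  invisible(x)
}

#' @export
coef.impairment_fit <- function(object, ...) {
  c(lin = object$lin_coeff, quad = object$quad_coeff)
}

#' @export
predict.impairment_fit <- function(object, drag, ...) {
  predict_impairment(object$lin_coeff, object$quad_coeff, drag,
                     fitted_range = object$drag_range)
}

#' Predict percent impairment for a given added drag
#'
#' Evaluates the through-origin quadratic `E = a F_D + b F_D^2`. Drags
#' outside the fitted range trigger an extrapolation warning but the value is
#' still returned.
#'
#' @param lin_coeff linear coefficient a (% N^-1).
#' @param quad_coeff quadratic coefficient b (% N^-2).
#' @param drag added drag force (N) at the reference speed; may be a vector.
#' @param fitted_range drag range (N) within which the model was calibrated.
#' @return predicted percent effect(s).
#' @examples
#' predict_impairment(102.8, 527.7, 0.159)  # ~29.7% Ucrit reduction
#' @export
predict_impairment <- function(lin_coeff, quad_coeff, drag,
                               fitted_range = c(0, 0.2)) {
  if (any(drag < 0)) stop("`drag` must be non-negative", call. = FALSE)
  if (any(drag > max(fitted_range) + 1e-12))
    warning("drag outside the fitted range [", fitted_range[1], ", ",
            fitted_range[2], "] N; extrapolating", call. = FALSE)
  lin_coeff * drag + quad_coeff * drag^2
}

#' Tag scenario for field predictions
#'
#' Describes an external tag by its drag at the reference speed and its
#' attachment site. Site A (0.125 body lengths from the snout, the most
#' posterior site of minimal lateral movement) carries no site penalty;
#' site B (the centre of mass, 0.35 body lengths, the traditional tag site)
#' adds fixed percentage-point increments on top of the drag effect. The
#' default increments are ~15 points extra reduction of critical swimming
#' speed and ~63 points extra increase of minimum cost of transport,
#' treating drag and site effects as additive.
#'
#' @param tag_drag drag of the tag (N) at the reference speed.
#' @param site attachment site, `"A"` or `"B"`.
#' @param site_ucrit_increment extra percentage points of Ucrit reduction at
#'   site B.
#' @param site_cotmin_increment extra percentage points of COTmin increase at
#'   site B.
#' @return an object of class `tag_scenario`.
#' @export
tag_scenario <- function(tag_drag, site = c("A", "B"),
                         site_ucrit_increment = 15,
                         site_cotmin_increment = 63) {
  site <- match.arg(site)
  if (tag_drag < 0) stop("`tag_drag` must be non-negative", call. = FALSE)
  if (site_ucrit_increment < 0 || site_cotmin_increment < 0)
    stop("site increments must be non-negative", call. = FALSE)
  structure(list(tag_drag = tag_drag, site = site,
                 site_ucrit_increment = site_ucrit_increment,
                 site_cotmin_increment = site_cotmin_increment),
            class = "tag_scenario")
}

#' Combine a drag effect with the attachment-site penalty
#'
#' Adds the site-B percentage-point increment for the given endpoint to a
#' drag-only prediction (additive model; site A leaves the prediction
#' unchanged). Additivity is an explicit assumption: if the interaction were
#' multiplicative the combined burden would be larger.
#'
#' @param drag_prediction percent effect predicted from drag alone.
#' @param scenario a [tag_scenario()].
#' @param endpoint `"ucrit"` or `"cotmin"`.
#' @return total percent effect.
#' @examples
#' combined_site_effect(29.68, tag_scenario(0.159, "B"), "ucrit")  # ~45%
#' @export
combined_site_effect <- function(drag_prediction, scenario,
                                 endpoint = c("ucrit", "cotmin")) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(scenario, "tag_scenario"))
  inc <- if (scenario$site == "B")
    switch(endpoint, ucrit = scenario$site_ucrit_increment,
           cotmin = scenario$site_cotmin_increment) else 0
  drag_prediction + inc
}

#' Reference impairment fits
#'
#' The published through-origin quadratic coefficients mapping added drag to
#' percent Ucrit reduction (a = 102.8, b = 527.7) and percent COTmin
#' increase (a = -8.92, b = 2687), with their standard errors, calibrated
#' over 0-0.2 N.
#'
#' @return a list with `impairment_fit` objects `ucrit` and `cotmin`.
#' @export
reference_impairment_fits <- function() {
  list(
    ucrit = structure(list(endpoint = "ucrit", lin_coeff = 102.8,
                           quad_coeff = 527.7,
                           coeff_se = c(lin = 49.35, quad = 273.8),
                           fit_r2 = 0.99, drag_range = c(0, 0.2),
                           n = 24L, pooled = TRUE),
                      class = "impairment_fit"),
    cotmin = structure(list(endpoint = "cotmin", lin_coeff = -8.92,
                            quad_coeff = 2687,
                            coeff_se = c(lin = 113, quad = 626.7),
                            fit_r2 = 0.99, drag_range = c(0, 0.2),
                            n = 24L, pooled = TRUE),
                       class = "impairment_fit"))
}

#' Where do the two impairment endpoints diverge?
#'
#' Critical swimming speed is the cheap field assay; minimum cost of
#' transport is the energetic quantity of interest. Their drag responses
#' agree at low drag but separate beyond ~0.1 N, where anaerobic
#' compensation keeps Ucrit from falling as fast as costs rise. This
#' tabulates both predictions over a drag grid and flags where they differ
#' by more than `threshold` percentage points.
#'
#' @param fit_ucrit an `impairment_fit` for the Ucrit endpoint.
#' @param fit_cotmin an `impairment_fit` for the COTmin endpoint.
#' @param drag_grid drag values (N) to evaluate.
#' @param threshold flag differences larger than this (percentage points).
#' @return a data frame with columns `drag`, `pred_ucrit`, `pred_cotmin`,
#'   `difference`, `flagged`.
#' @export
endpoint_divergence <- function(fit_ucrit, fit_cotmin,
                                drag_grid = seq(0.05, 0.2, 0.05),
                                threshold = 10) {
  pu <- predict(fit_ucrit, drag_grid)
  pc <- predict(fit_cotmin, drag_grid)
  data.frame(drag = drag_grid, pred_ucrit = pu, pred_cotmin = pc,
             difference = pc - pu, flagged = abs(pc - pu) > threshold)
}

#' Evaluate a tag scenario against fitted impairment models
#'
#' One-stop field calculator: predicts the drag-only percent effect on both
#' endpoints, applies the attachment-site increment, and reports whether the
#' tag's drag lies outside the calibrated range.
#'
#' @param scenario a [tag_scenario()].
#' @param fits list with `impairment_fit` objects `ucrit` and `cotmin`;
#'   defaults to [reference_impairment_fits()].
#' @return a list with per-endpoint components `drag_effect`, `site_effect`,
#'   `total`, plus `extrapolation_flag`.
#' @examples
#' evaluate_tag(tag_scenario(0.159, "B"))
#' @export
evaluate_tag <- function(scenario, fits = reference_impairment_fits()) {
  stopifnot(inherits(scenario, "tag_scenario"))
  extrap <- scenario$tag_drag > max(fits$ucrit$drag_range)
  du <- withCallingHandlers(predict(fits$ucrit, scenario$tag_drag),
                            warning = function(w) invokeRestart("muffleWarning"))
  dc <- withCallingHandlers(predict(fits$cotmin, scenario$tag_drag),
                            warning = function(w) invokeRestart("muffleWarning"))
  su <- combined_site_effect(du, scenario, "ucrit") - du
  sc <- combined_site_effect(dc, scenario, "cotmin") - dc
  list(tag_drag = scenario$tag_drag, site = scenario$site,
       ucrit = list(drag_effect = du, site_effect = su, total = du + su),
       cotmin = list(drag_effect = dc, site_effect = sc, total = dc + sc),
       extrapolation_flag = extrap)
}
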