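#' Fluid environment for drag calculations
#'
#' Bundles the physical constants of the swim-tunnel water and the reference
#' speed at which nominal tag drags are defined. Defaults describe seawater
#' (density 1020 kg m^-3), the drag coefficient of a sphere (0.45), and a
#' reference speed of 0.65 m s^-1, the optimal swimming speed of untagged
#' silver eels at which drag dummies are sized.
#'
#' @param density mass density of the fluid (kg m^-3).
#' @param drag_coefficient dimensionless drag coefficient of the towed body;
#'   0.45 for a sphere at the Reynolds numbers of interest.
#' @param reference_speed speed (m s^-1) at which nominal drag forces are
#'   quoted.
#' @return an object of class `fluid_env`.
#' @examples
#' env <- fluid_env()
#' sphere_drag(0.0362, 0.65, env)
#' @export
fluid_env <- function(density = 1020, drag_coefficient = 0.45,
                      reference_speed = 0.65) {
  if (!is.numeric(density) || density <= 0)
    stop("`density` must be a positive number", call. = FALSE)
  if (!is.numeric(drag_coefficient) || drag_coefficient <= 0 ||
      drag_coefficient >= 2)
    stop("`drag_coefficient` must lie in (0, 2)", call. = FALSE)
  if (!is.numeric(reference_speed) || reference_speed <= 0)
    stop("`reference_speed` must be positive", call. = FALSE)
  structure(list(density = density, drag_coefficient = drag_coefficient,
                 reference_speed = reference_speed),
            class = "fluid_env")
}

#' @export
print.fluid_env <- function(x, ...) {
  cat(sprintf(
    "Fluid environment: rho = %g kg m^-3, c_D = %g, V_ref = %g m s^-1\n",
    x$density, x$drag_coefficient, x$reference_speed))
  invisible(x)
}

#' Drag force of a sphere
#'
#' Shape drag of a sphere of given diameter towed at a given speed,
#' `F = 1/2 rho V^2 c_D A`, with `A` the cross-sectional area `pi (d/2)^2`.
#' Spheres are used as drag dummies because their drag is dominated by shape
#' drag rather than surface friction, so the force follows directly from the
#' diameter.
#'
#' @param diameter sphere diameter (m); may be a vector.
#' @param speed water speed (m s^-1); may be a vector.
#' @param env a [fluid_env()].
#' @return drag force (N).
#' @seealso [size_sphere()] for the inverse problem.
#' @export
sphere_drag <- function(diameter, speed, env = fluid_env()) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("`diameter` must be positive", call. = FALSE)
  if (any(!is.finite(speed)) || any(speed < 0))
    stop("`speed` must be non-negative", call. = FALSE)
  0.5 * env$density * speed^2 * env$drag_coefficient * pi * (diameter / 2)^2
}

#' Size a spherical drag dummy for a target drag force
#'
#' Inverts the sphere drag law at the reference speed:
#' `d = sqrt(8 F / (rho c_D pi V_ref^2))`. With the default environment this
#' reproduces the standard dummy sizes: 2.56 cm for 0.05 N, 3.62 cm for
#' 0.1 N and 5.12 cm for 0.2 N.
#'
#' @param target_drag desired drag force (N) at the reference speed; may be a
#'   vector.
#' @param env a [fluid_env()].
#' @return sphere diameter (m).
#' @examples
#' round(100 * size_sphere(c(0.05, 0.1, 0.2)), 2)
#' @export
size_sphere <- function(target_drag, env = fluid_env()) {
  if (any(!is.finite(target_drag)) || any(target_drag <= 0))
    stop("`target_drag` must be positive", call. = FALSE)
  sqrt(8 * target_drag /
         (env$density * env$drag_coefficient * pi * env$reference_speed^2))
}

#' Drag-dummy specification
#'
#' @param label size-class label, e.g. `"small"`, `"intermediate"`, `"large"`.
#' @param diameter sphere diameter (m).
#' @param nominal_drag drag force (N) at the reference speed.
#' @return an object of class `dummy_spec`.
#' @export
dummy_spec <- function(label, diameter, nominal_drag) {
  if (diameter <= 0) stop("`diameter` must be positive", call. = FALSE)
  if (nominal_drag <= 0) stop("`nominal_drag` must be positive", call. = FALSE)
  structure(list(label = as.character(label), diameter = diameter,
                 nominal_drag = nominal_drag),
            class = "dummy_spec")
}

#' @export
print.dummy_spec <- function(x, ...) {
  cat(sprintf("Drag dummy '%s': d = %.2f cm, nominal %g N\n",
              x$label, 100 * x$diameter, x$nominal_drag))
  invisible(x)
}

#' Construct an empirical drag curve
#'
#' A calibrated force-speed relation `F(V) = quad V^2 + lin V`, fit through
#' the origin (zero speed must give zero force). Usually produced by
#' [fit_drag_curve()]; this constructor also admits published coefficient
#' pairs.
#'
#' @param quad_coeff coefficient of `V^2` (N s^2 m^-2).
#' @param lin_coeff coefficient of `V` (N s m^-1).
#' @param fit_r2 coefficient of determination of the calibration fit.
#' @param speed_range numeric length-2, span of the calibration speeds
#'   (m s^-1).
#' @return an object of class `drag_curve`.
#' @export
drag_curve <- function(quad_coeff, lin_coeff, fit_r2 = NA_real_,
                       speed_range = c(0.2, 0.9)) {
  if (!is.na(fit_r2) && (fit_r2 < 0 || fit_r2 > 1))
    stop("`fit_r2` must lie in [0, 1]", call. = FALSE)
  structure(list(quad_coeff = quad_coeff, lin_coeff = lin_coeff,
                 fit_r2 = fit_r2, speed_range = sort(speed_range)),
            class = "drag_curve")
}

#' Fit an empirical drag curve from calibration measurements
#'
#' Least-squares fit of `F = quad V^2 + lin V` (no constant term) to force
#' measurements taken across a range of tunnel speeds. Replicate measurements
#' at the same speed are averaged before fitting by default, matching the
#' usual calibration workflow of measuring each speed in triplicate.
#'
#' @param speed tunnel speeds (m s^-1).
#' @param force measured drag forces (N).
#' @param replicate optional replicate identifiers; unused beyond bookkeeping.
#' @param average_replicates average forces per distinct speed before fitting
#'   (default), or fit all raw points.
#' @return a `drag_curve` with coefficients, `fit_r2` and the calibration
#'   `speed_range`.
#' @examples
#' v <- seq(0.2, 0.9, 0.1)
#' fit_drag_curve(v, 0.341 * v^2 - 0.065 * v)
#' @export
fit_drag_curve <- function(speed, force, replicate = NULL,
                           average_replicates = TRUE) {
  if (length(speed) != length(force))
    stop("`speed` and `force` must have equal length", call. = FALSE)
  if (length(unique(speed)) < 3)
    stop("need measurements at >= 3 distinct speeds", call. = FALSE)
  if (average_replicates) {
    force <- tapply(force, speed, mean)
    speed <- as.numeric(names(force))
    force <- as.numeric(force)
  }
  fit <- stats::lm(force ~ 0 + I(speed^2) + speed)
  res <- stats::residuals(fit)
  sst <- sum((force - mean(force))^2)
  r2 <- if (sst <= .Machine$double.eps * sum(force^2) || sst == 0) 0 else
    max(0, min(1, 1 - sum(res^2) / sst))
  cf <- stats::coef(fit)
  drag_curve(unname(cf[1]), unname(cf[2]), fit_r2 = r2,
             speed_range = range(speed))
}

#' @export
print.drag_curve <- function(x, ...) {
  cat(sprintf("Empirical drag curve: F = %.4g V^2 %+.4g V  (r^2 = %s)\n",
              x$quad_coeff, x$lin_coeff,
              ifelse(is.na(x$fit_r2), "NA", sprintf("%.3f", x$fit_r2))))
  cat(sprintf("  calibrated over V in [%.2g, %.2g] m s^-1\n",
              x$speed_range[1], x$speed_range[2]))
  invisible(x)
}

#' @export
coef.drag_curve <- function(object, ...) {
  c(quad = object$quad_coeff, lin = object$lin_coeff)
}

#' Evaluate a drag curve at given speeds
#'
#' @param object a `drag_curve`.
#' @param speed speeds (m s^-1) at which to evaluate the curve.
#' @param ... unused.
#' @return predicted drag force (N). Warns when `speed` lies outside the
#'   calibration range (the value is still returned).
#' @export
predict.drag_curve <- function(object, speed, ...) {
  if (any(speed < object$speed_range[1] - 1e-12) ||
      any(speed > object$speed_range[2] + 1e-12))
    warning("speed outside calibration range [",
            object$speed_range[1], ", ", object$speed_range[2],
            "] m s^-1; extrapolating", call. = FALSE)
  object$quad_coeff * speed^2 + object$lin_coeff * speed
}

#' Relative difference between theoretical and calibrated drag
#'
#' Compares the sphere drag law for a dummy's diameter with its empirically
#' calibrated drag curve at a given speed, as
#' `|theory - empirical| / theory`. Used to check that the shape-drag
#' approximation holds for a manufactured dummy (agreement within 5% at the
#' reference speed is typical).
#'
#' @param curve a `drag_curve`.
#' @param spec a [dummy_spec()].
#' @param env a [fluid_env()].
#' @param speed evaluation speed (m s^-1); defaults to the reference speed.
#' @return the relative difference (fraction).
#' @export
drag_agreement <- function(curve, spec, env = fluid_env(),
                           speed = env$reference_speed) {
  theory <- sphere_drag(spec$diameter, speed, env)
  empirical <- predict(curve, speed)
  abs(theory - empirical) / theory
}

#' Reference drag dummies and their calibration curves
#'
#' The three standard spherical dummies (small 0.05 N, intermediate 0.1 N,
#' large 0.2 N at 0.65 m s^-1) with their published diameters and empirically
#' calibrated force-speed polynomials, valid over 0.2-0.9 m s^-1.
#'
#' @return a named list, one element per size class, each holding a
#'   `dummy_spec` and a `drag_curve`.
#' @examples
#' ref <- reference_dummies()
#' drag_agreement(ref$intermediate$curve, ref$intermediate$spec)
#' @export
reference_dummies <- function() {
  list(
    small = list(
      spec  = dummy_spec("small", 0.0256, 0.05),
      curve = drag_curve(0.123, -0.004, fit_r2 = 0.99)),
    intermediate = list(
      spec  = dummy_spec("intermediate", 0.0362, 0.10),
      curve = drag_curve(0.341, -0.065, fit_r2 = 0.99)),
    large = list(
      spec  = dummy_spec("large", 0.0513, 0.20),
      curve = drag_curve(0.56, -0.068, fit_r2 = 0.99))
  )
}
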