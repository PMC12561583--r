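#' Differentiate a uniformly sampled series
#'
#' Central differences on interior samples, two-point one-sided differences at
#' the ends. For a joint-angle series in degrees sampled at `dt` seconds this
#' gives angular velocity in degrees per second.
#'
#' @param x Numeric series, length >= 3, uniformly sampled.
#' @param dt Sample spacing in seconds (> 0).
#' @return Numeric series of the same length as `x`.
#' @export
differentiate <- function(x, dt) {
  stopifnot(is.numeric(x), is.numeric(dt), length(dt) == 1L, dt > 0)
  n <- length(x)
  if (n < 3L) {
    stop("differentiate() needs at least 3 samples, got ", n, call. = FALSE)
  }
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) / dt
  v[n] <- (x[n] - x[n - 1L]) / dt
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  v
}

#' Amplitude-normalize an angle/velocity pair for the phase portrait
#'
#' Rescales the angle to \[-1, 1\] by its min-max range and the velocity by its
#' maximum absolute value, so the phase angle of the portrait point
#' (x_norm, v_norm) is comparable across joints, subjects, and movement
#' amplitudes. The velocity keeps its sign (dividing by max |v|): a min-max
#' rescale of velocity would shift the phase-plane origin away from zero
#' velocity and distort the phase angle.
#'
#' @param angle Angle series (degrees); must have non-zero range.
#' @param velocity Velocity series (degrees/s), same length; must not be
#'   identically zero.
#' @return List with components `x_norm` and `v_norm`, both in \[-1, 1\].
#' @export
normalize_amplitude <- function(angle, velocity) {
  stopifnot(is.numeric(angle), is.numeric(velocity))
  if (length(angle) != length(velocity)) {
    stop("angle and velocity must have equal length", call. = FALSE)
  }
  rng <- range(angle)
  if (!all(is.finite(rng)) || diff(rng) <= 0) {
    stop("degenerate signal: angle series has zero range (frozen joint has no defined phase)",
         call. = FALSE)
  }
  vmax <- max(abs(velocity))
  if (!is.finite(vmax) || vmax <= 0) {
    stop("degenerate signal: velocity is identically zero", call. = FALSE)
  }
  list(
    x_norm = 2 * (angle - rng[1L]) / (rng[2L] - rng[1L]) - 1,
    v_norm = velocity / vmax
  )
}

#' Phase angle of a normalized phase-portrait trajectory
#'
#' Per-sample four-quadrant angle of the portrait point (x_norm, v_norm):
#' 0 degrees at maximal angle with zero velocity, 90 degrees at zero angle with
#' maximal positive velocity. The sequence is unwrapped so adjacent samples
#' never jump by 180 degrees or more.
#'
#' @param x_norm,v_norm Output of [normalize_amplitude()].
#' @return Unwrapped phase-angle series in degrees.
#' @export
phase_angle <- function(x_norm, v_norm) {
  stopifnot(length(x_norm) == length(v_norm))
  zero <- which(x_norm == 0 & v_norm == 0)
  if (length(zero) > 0L) {
    stop("phase undefined at the phase-plane origin (sample ",
         paste(zero, collapse = ", "), ")", call. = FALSE)
  }
  phi <- atan2(v_norm, x_norm)
  signal::unwrap(phi) * 180 / pi
}

# Shift an unwrapped angle series by a multiple of 360 so its first sample
# lies in (-180, 180]. Both CRP routes use this, so their branch choice at
# theta = +/-180 coincides.
canonicalize_branch <- function(theta) {
  k <- ceiling((theta[1L] - 180) / 360)
  theta - 360 * k
}

#' Continuous relative phase from two phase-angle series
#'
#' Pointwise difference distal minus proximal, in degrees. Positive values mean
#' the distal joint leads (is in pre-phase relative to) the proximal joint;
#' zero means the joints move perfectly in phase. The result is shifted by a
#' multiple of 360 degrees so it starts in (-180, 180].
#'
#' @param phi_distal,phi_proximal Unwrapped phase-angle series (degrees) from
#'   [phase_angle()], equal lengths.
#' @return Relative-phase series theta in degrees.
#' @export
relative_phase <- function(phi_distal, phi_proximal) {
  if (length(phi_distal) != length(phi_proximal)) {
    stop("phase-angle series lengths differ (",
         length(phi_distal), " vs ", length(phi_proximal), ")", call. = FALSE)
  }
  canonicalize_branch(phi_distal - phi_proximal)
}

#' Continuous relative phase directly from two angle series
#'
#' Single-formula route: both series are amplitude-normalized along with their
#' derivatives, and the relative phase is the four-quadrant arctangent
#' \deqn{\theta_i = \mathrm{atan2}(\dot{x}_{1}x_{2} - \dot{x}_{2}x_{1},\;
#'       x_{1}x_{2} + \dot{x}_{1}\dot{x}_{2})}
#' (all terms normalized), unwrapped. This is the polar-angle difference of the
#' two phase-portrait points, so on narrowband signals it agrees with
#' [phase_angle()] + [relative_phase()] to machine precision.
#'
#' The plus sign in the second argument is required for the identity
#' \eqn{\theta \equiv 0} when the two series coincide (completely in-phase
#' joints). `denominator = "printed"` selects a minus-sign variant found in
#' some write-ups of the formula; it is provided for auditing only and does
#' not satisfy the in-phase identity.
#'
#' @param x1 Distal joint angle series (degrees).
#' @param x2 Proximal joint angle series (degrees), same length, length >= 3.
#' @param dt Sample spacing in seconds.
#' @param denominator `"standard"` (plus sign, default) or `"printed"`.
#' @return Relative-phase series theta in degrees, starting in (-180, 180].
#' @export
relative_phase_direct <- function(x1, x2, dt, denominator = c("standard", "printed")) {
  denominator <- match.arg(denominator)
  if (length(x1) != length(x2)) {
    stop("angle series lengths differ (", length(x1), " vs ", length(x2), ")",
         call. = FALSE)
  }
  n1 <- normalize_amplitude(x1, differentiate(x1, dt))
  n2 <- normalize_amplitude(x2, differentiate(x2, dt))
  num <- n1$v_norm * n2$x_norm - n2$v_norm * n1$x_norm
  den <- if (denominator == "standard") {
    n1$x_norm * n2$x_norm + n1$v_norm * n2$v_norm
  } else {
    n1$x_norm * n2$x_norm - n1$v_norm * n2$v_norm
  }
  theta <- signal::unwrap(atan2(num, den)) * 180 / pi
  canonicalize_branch(theta)
}

#' Resample a series onto a uniform 0-100% movement-cycle grid
#'
#' Linear interpolation onto `n_points` equally spaced cycle fractions from 0
#' to 100% inclusive; the first and last input samples map exactly to 0% and
#' 100%. This is the usual time normalization that lets cycles of different
#' durations be averaged pointwise.
#'
#' @param values Numeric series, length >= 4, assumed uniformly sampled over
#'   one movement cycle.
#' @param n_points Grid size N (>= 11); 101 is the field convention.
#' @return A `normalized_cycle`: list with `n_points`, `cycle_fraction`
#'   (percent, 0 to 100), and `values` (length N).
#' @export
time_normalize <- function(values, n_points = 101L) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) {
    stop("time_normalize() needs at least 4 samples", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 11L) {
    stop("n_points must be an integer >= 11, got ", n_points, call. = FALSE)
  }
  src <- seq(0, 100, length.out = length(values))
  grid <- seq(0, 100, length.out = n_points)
  out <- stats::approx(src, values, xout = grid)$y
  structure(
    list(n_points = n_points, cycle_fraction = grid, values = out),
    class = "normalized_cycle"
  )
}

#' Continuous relative phase curve for one coupling of a trial
#'
#' Full per-trial pipeline: differentiate both joints, amplitude-normalize,
#' take phase-plane angles, difference them (distal minus proximal), and
#' time-normalize the resulting relative-phase curve onto the 0-100% cycle
#' grid.
#'
#' @param trial An `angle_trial` from [read_trial_table()] or
#'   [simulate_joint_cycle()].
#' @param coupling Character vector `c(distal, proximal)` naming two joints
#'   present in the trial, e.g. `c("ankle", "knee")`.
#' @param n_points Cycle grid size (default 101).
#' @param method `"phase_angle"` (two phase angles differenced, default) or
#'   `"direct"` (single arctangent formula); the two agree on narrowband
#'   signals.
#' @return A `crp_curve`: list with `coupling`, `cycle_fraction`, `theta`
#'   (degrees), and provenance fields (`subject_id`, `group`, `stage`,
#'   `trial_index`).
#' @export
crp_curve <- function(trial, coupling, n_points = 101L,
                      method = c("phase_angle", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(trial, "angle_trial"), length(coupling) == 2L)
  missing_joints <- setdiff(coupling, names(trial$angles))
  if (length(missing_joints) > 0L) {
    stop("trial has no joint(s): ", paste(missing_joints, collapse = ", "),
         call. = FALSE)
  }
  dt <- 1 / trial$sample_rate
  xd <- trial$angles[[coupling[1L]]]
  xp <- trial$angles[[coupling[2L]]]
  theta <- if (method == "direct") {
    relative_phase_direct(xd, xp, dt)
  } else {
    pd <- normalize_amplitude(xd, differentiate(xd, dt))
    pp <- normalize_amplitude(xp, differentiate(xp, dt))
    relative_phase(phase_angle(pd$x_norm, pd$v_norm),
                   phase_angle(pp$x_norm, pp$v_norm))
  }
  cyc <- time_normalize(theta, n_points)
  structure(
    list(
      coupling = coupling,
      cycle_fraction = cyc$cycle_fraction,
      theta = cyc$values,
      subject_id = trial$subject_id,
      group = trial$group,
      stage = trial$stage,
      trial_index = trial$trial_index
    ),
    class = "crp_curve"
  )
}
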