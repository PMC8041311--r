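# coupling_analysis: theta/Z rotation-translation coupling, mechanism
# classification, and MSD-based diffusion coefficients.

resolve_selection <- function(traj, selection) {
  nb <- dim(traj$coords)[2]
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > nb)) stopf("selection indices out of 1..%d", nb)
    return(list(idx = idx, label = sprintf("beads[%d]", length(idx))))
  }
  if (identical(selection, "protein")) {
    return(list(idx = seq_len(nb), label = "protein"))
  }
  if (grepl("^chain:", selection)) {
    ch <- sub("^chain:", "", selection)
    if (is.null(traj$beads)) stopf("trajectory has no bead table; select by index")
    idx <- which(traj$beads$chain == ch)
    if (!length(idx)) stopf("no beads on chain '%s'", ch)
    return(list(idx = idx, label = selection))
  }
  stopf("unknown selection '%s'", selection)
}

#' Rotation angle and axial position of the tracked centre of mass
#'
#' For each frame, computes the centre of mass of the selected beads, its
#' height Z along the DNA axis, and its azimuthal angle theta around the
#' axis from the two-argument arctangent of (y, x). Raw angles are
#' unwrapped: jumps larger than pi between successive frames are corrected
#' by +/- 2 pi so that multi-turn rotation accumulates continuously. For a
#' ring protein such as a sliding clamp, track one monomer (e.g.
#' `selection = "chain:A"`) -- the whole-trimer COM sits on the axis where
#' the angle is undefined.
#'
#' @param traj A `Trajectory`.
#' @param selection "protein" (all beads), "chain:X", or bead indices.
#' @return An `AngularTrace`: data.frame(time, z, theta) with the selection
#'   label and radial distance attached.
#' @export
angular_trace <- function(traj, selection = "protein") {
  sel <- resolve_selection(traj, selection)
  co <- traj$coords[, sel$idx, , drop = FALSE]
  com <- apply(co, c(1, 3), mean)
  r <- sqrt(com[, 1]^2 + com[, 2]^2)
  if (any(r < 1e-9)) {
    stopf("tracked COM lies on the DNA axis (x = y = 0); angle undefined")
  }
  theta <- unwrap_angle(atan2(com[, 2], com[, 1]))
  structure(data.frame(time = traj$times, z = com[, 3], theta = theta,
                       radius = r),
            selection = sel$label, class = c("AngularTrace", "data.frame"))
}

#' Unwrap a wrapped angle series
#'
#' Adds multiples of 2 pi so that successive differences never exceed pi in
#' magnitude; inverse of wrapping to (-pi, pi] up to a global 2 pi constant.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Unwrapped angle vector.
#' @export
unwrap_angle <- function(theta) {
  d <- diff(theta)
  corr <- cumsum(-2 * pi * round(d / (2 * pi)))
  c(theta[1], theta[-1] + corr)
}

default_bands <- function() {
  list(sliding = c(-0.21, -0.15), hopping_max = 0.05)
}

classify_slope <- function(slope, bands = default_bands()) {
  if (!is.finite(slope)) return("undetermined")
  if (slope >= bands$sliding[1] && slope <= bands$sliding[2]) return("sliding")
  if (abs(slope) <= bands$hopping_max) return("hopping")
  "intermediate"
}

#' Fit the theta/Z coupling line
#'
#' Ordinary least squares of theta on Z over all frames. A slope near
#' -2*pi/34 = -0.185 rad/A means the protein advances one full turn per
#' helical pitch: rotation-coupled translation (sliding). A slope near 0
#' means translation without net rotation (hopping).
#'
#' @param trace An `AngularTrace`.
#' @param bands Classification thresholds: list(sliding = c(lo, hi),
#'   hopping_max = h). Defaults: sliding for slope in [-0.21, -0.15],
#'   hopping for |slope| <= 0.05, otherwise intermediate.
#' @return A `CouplingResult`: slope (rad/A), standard error, intercept,
#'   r_squared, n, classification.
#' @export
fit_theta_z <- function(trace, bands = default_bands()) {
  n <- nrow(trace)
  if (n < 10L) stopf("need at least 10 frames, got %d", n)
  zr <- diff(range(trace$z))
  if (zr < 1e-9 || sd(trace$z) < 1e-12) {
    return(structure(list(slope = NA_real_, se = NA_real_,
                          intercept = NA_real_, r_squared = NA_real_,
                          n = n, classification = "undetermined",
                          bands = bands),
                     class = "CouplingResult"))
  }
  z <- trace$z; th <- trace$theta
  zc <- z - mean(z)
  slope <- sum(zc * th) / sum(zc^2)
  intercept <- mean(th) - slope * mean(z)
  res <- th - intercept - slope * z
  ss_res <- sum(res^2)
  ss_tot <- sum((th - mean(th))^2)
  se <- sqrt(ss_res / (n - 2) / sum(zc^2))
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = slope, se = se, intercept = intercept,
                 r_squared = r2, n = n,
                 classification = classify_slope(slope, bands),
                 bands = bands),
            class = "CouplingResult")
}

#' @export
print.CouplingResult <- function(x, ...) {
  cat(sprintf(
    "CouplingResult: slope %.4f +/- %.4f rad/A (R2 %.3f, n %d) -> %s\n",
    x$slope, x$se, x$r_squared %||% NA, x$n, x$classification))
  invisible(x)
}

#' Aggregate coupling fits across replicate trajectories
#'
#' Unweighted mean of the per-trajectory theta/Z slopes with its standard
#' error across replicates (the convention used when error bars are
#' estimated from independent simulations), classified with the same bands
#' as [fit_theta_z()]. Undetermined replicates are dropped.
#'
#' @param results List of `CouplingResult`s (or a single one).
#' @param bands See [fit_theta_z()].
#' @return A `MechanismSummary`: mean_slope, se, n, classification.
#' @export
classify_mechanism <- function(results, bands = default_bands()) {
  if (inherits(results, "CouplingResult")) results <- list(results)
  if (length(results) == 0L) stopf("no coupling results supplied")
  slopes <- vapply(results, function(r) r$slope, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) == 0L) {
    return(structure(list(mean_slope = NA_real_, se = NA_real_, n = 0L,
                          classification = "undetermined"),
                     class = "MechanismSummary"))
  }
  m <- mean(slopes)
  se <- if (length(slopes) > 1) sd(slopes) / sqrt(length(slopes)) else NA_real_
  structure(list(mean_slope = m, se = se, n = length(slopes),
                 classification = classify_slope(m, bands)),
            class = "MechanismSummary")
}

#' @export
print.MechanismSummary <- function(x, ...) {
  cat(sprintf("MechanismSummary: mean slope %.4f +/- %.4f rad/A (n=%d) -> %s\n",
              x$mean_slope, x$se, x$n, x$classification))
  invisible(x)
}

#' Mean-square displacement and diffusion coefficient
#'
#' Sliding-origin MSD, `MSD(tau) = mean over t0 of |r(t0+tau) - r(t0)|^2`,
#' for the tracked COM, with a linear fit `MSD = 2 d D tau` over the
#' configured lag window (default lag indices 1 to 200 at the saved
#' stride). The default dimensionality d = 1 uses the Z coordinate: linear
#' diffusion along the DNA. `d = 3` uses the full COM. A curvature check
#' flags traces whose MSD is visibly non-linear over the window (e.g.
#' ballistic motion), where a single D is not meaningful.
#'
#' @param x An `AngularTrace`, a `Trajectory` (COM of all beads), a numeric
#'   vector (1D coordinate series) or a matrix of coordinates.
#' @param d Dimensionality of diffusion (1 uses Z / the vector; 3 the full
#'   coordinates).
#' @param fit_window Lag-index window c(lo, hi) for the linear fit.
#' @param dt Frame spacing in time units (taken from the trace/trajectory
#'   when available; default 1).
#' @return An `MSDResult`: tau, msd, D, slope, fit_window, d, nonlinear.
#' @export
msd <- function(x, d = 1, fit_window = c(1, 200), dt = NULL) {
  if (inherits(x, "Trajectory")) {
    co <- apply(x$coords, c(1, 3), mean)
    dt <- dt %||% (if (length(x$times) > 1) diff(x$times[1:2]) else 1)
    m <- if (d == 1) co[, 3, drop = FALSE] else co
  } else if (inherits(x, "AngularTrace")) {
    dt <- dt %||% (if (nrow(x) > 1) x$time[2] - x$time[1] else 1)
    if (d != 1) stopf("an AngularTrace supports d = 1 (Z) only")
    m <- matrix(x$z, ncol = 1)
  } else if (is.numeric(x) && is.null(dim(x))) {
    m <- matrix(x, ncol = 1)
    dt <- dt %||% 1
  } else {
    m <- as.matrix(x)
    dt <- dt %||% 1
  }
  if (d == 1 && ncol(m) != 1) m <- m[, ncol(m), drop = FALSE]
  n <- nrow(m)
  if (fit_window[2] >= n) {
    stopf("fit window [%d, %d] exceeds trajectory length %d",
          fit_window[1], fit_window[2], n)
  }
  max_lag <- min(n - 1L, max(fit_window[2], min(n - 1L, 4L * fit_window[2])))
  tau_idx <- seq_len(max_lag)
  msd_v <- vapply(tau_idx, function(lag) {
    dd <- m[(1 + lag):n, , drop = FALSE] - m[1:(n - lag), , drop = FALSE]
    mean(rowSums(dd * dd))
  }, numeric(1))
  tau <- tau_idx * dt
  w <- fit_window[1]:fit_window[2]
  zc <- tau[w] - mean(tau[w])
  slope <- sum(zc * msd_v[w]) / sum(zc^2)
  D <- max(slope, 0) / (2 * d)
  # curvature check: quadratic term significant relative to linear fit
  qfit <- lm(msd_v[w] ~ tau[w] + I(tau[w]^2))
  quad <- coef(qfit)[3]
  nonlinear <- is.finite(quad) &&
    abs(quad) * diff(range(tau[w]))^2 > 0.5 * abs(slope) * diff(range(tau[w]))
  structure(list(tau = c(0, tau), msd = c(0, msd_v), D = D, slope = slope,
                 fit_window = fit_window, d = d, dt = dt,
                 nonlinear = nonlinear),
            class = "MSDResult")
}

#' @export
print.MSDResult <- function(x, ...) {
  cat(sprintf("MSDResult: D = %.4g A^2/time (d = %d, lags %d..%d%s)\n",
              x$D, x$d, x$fit_window[1], x$fit_window[2],
              if (x$nonlinear) ", NONLINEAR over window" else ""))
  invisible(x)
}
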