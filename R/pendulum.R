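#' Trifilar pendulum rig
#'
#' Geometry and mass of a trifilar pendulum: a platform suspended by three
#' parallel threads of length `L` attached at radius `R` from the rotation
#' center.  Small torsional oscillations behave as a single-degree-of-freedom
#' system whose period yields the platform's moment of inertia.
#'
#' @param m_p pendulum mass without the specimen, kg.
#' @param R thread attachment radius from the rotation center, m.
#' @param L mean thread length, m.
#' @param g gravitational acceleration, m s^-2 (default 9.81).
#' @param I_p rig MoI without the specimen, kg m^2, once measured (optional).
#' @return object of class `pendulum_rig`.
#' @export
pendulum_rig <- function(m_p, R, L, g = 9.81, I_p = NA_real_) {
  stopifnot(m_p > 0, R > 0, L > 0)
  if (g < 9.7 || g > 9.9)
    stop("g = ", g, " m s^-2 is outside plausible terrestrial values", call. = FALSE)
  structure(list(m_p = m_p, R = R, L = L, g = g, I_p = I_p),
            class = "pendulum_rig")
}

#' @export
print.pendulum_rig <- function(x, ...) {
  cat("<pendulum_rig> m_p = ", x$m_p, " kg, R = ", x$R, " m, L = ", x$L,
      " m, g = ", x$g, " m s^-2",
      if (!is.na(x$I_p)) paste0(", I_p = ", signif(x$I_p, 6), " kg m^2"),
      "\n", sep = "")
  invisible(x)
}

#' Angular-velocity oscillation trace
#'
#' @param t time, s, uniformly sampled.
#' @param omega angular velocity, rad s^-1.
#' @return object of class `oscillation_trace` with fields `t`, `omega`,
#'   `rate` (Hz).
#' @export
oscillation_trace <- function(t, omega) {
  stopifnot(length(t) == length(omega), length(t) >= 2L)
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9)
    stop("trace must be uniformly sampled (to 1e-9 s)", call. = FALSE)
  structure(list(t = as.numeric(t), omega = as.numeric(omega),
                 rate = 1 / mean(dt)),
            class = "oscillation_trace")
}

#' Read a gyroscope log CSV
#'
#' Tolerant of common smartphone-logger header variants: the time column may
#' be named `time_s`, `time`, `t`, `timestamp` and the angular-velocity
#' column `omega_rad_s`, `omega`, `gyro_z`, `wz`, `angular_velocity`
#' (case-insensitive).
#'
#' @param path CSV file path.
#' @return an [oscillation_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(trimws(names(df)))
  t_col <- match(TRUE, nm %in% c("time_s", "time", "t", "timestamp", "time (s)"))
  w_col <- match(TRUE, nm %in% c("omega_rad_s", "omega", "gyro_z", "wz",
                                 "angular_velocity", "omega (rad/s)"))
  if (is.na(t_col) || is.na(w_col))
    stop("could not identify time / angular-velocity columns in ", path,
         " (found: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
  oscillation_trace(df[[t_col]], df[[w_col]])
}

#' Fit a damped harmonic oscillator to an angular-velocity trace
#'
#' Nonlinear least squares of the damped-oscillator angular-velocity model
#' \deqn{\omega(t) = X e^{-\zeta\omega_n t}\,[\omega_d\cos(\omega_d t + \phi)
#'   - \zeta\omega_n \sin(\omega_d t + \phi)]}
#' (the derivative of `x(t) = X exp(-zeta omega_n t) sin(omega_d t + phi)`,
#' since the gyroscope observes angular velocity) over the trailing
#' `fit_window` seconds of the trace, skipping startup transients.  Initial
#' guesses: `omega_d` from the dominant discrete-spectrum peak, `zeta` from
#' the log-decrement of successive extrema, `X` and `phi` from the first
#' fitted cycle.
#'
#' @param trace an [oscillation_trace()].
#' @param fit_window seconds from the end of the trace to fit (default 60).
#' @return object of class `damped_fit`: `zeta`, `omega_n`, `omega_d`, `X`
#'   (rad), `phi` (rad), `tau` (= 2 pi / omega_d, s), `residual_rms`
#'   (rad s^-1), and the `window` fitted.
#' @export
fit_damped_oscillator <- function(trace, fit_window = 60) {
  stopifnot(inherits(trace, "oscillation_trace"))
  t_end <- trace$t[length(trace$t)]
  if (fit_window >= t_end - trace$t[1L])
    stop("trace is shorter than the fit window", call. = FALSE)
  keep <- trace$t >= t_end - fit_window
  tt <- trace$t[keep] - (t_end - fit_window)
  ww <- trace$omega[keep]
  n <- length(tt); dt <- 1 / trace$rate

  # spectral peak for the initial damped frequency, refined by parabolic
  # interpolation so the phase drift over the window stays small
  spec <- Mod(stats::fft(ww - mean(ww)))[seq_len(floor(n / 2))]
  pk <- which.max(spec[-1L]) + 1L
  if (!is.finite(spec[pk]) || pk < 2L ||
      spec[pk] < 5 * stats::median(spec[-1L]))
    stop("no oscillation detected: spectral peak indistinguishable from ",
         "the noise floor", call. = FALSE)
  delta <- 0
  if (pk > 2L && pk < length(spec)) {
    a <- spec[pk - 1L]; b <- spec[pk]; cc <- spec[pk + 1L]
    if (a - 2 * b + cc < 0) delta <- max(-0.5, min(0.5, 0.5 * (a - cc) / (a - 2 * b + cc)))
  }
  w_d0 <- 2 * pi * (pk - 1L + delta) / (n * dt)
  if (!is.finite(w_d0) || w_d0 <= 0)
    stop("no oscillation detected: spectral peak indistinguishable from ",
         "the noise floor", call. = FALSE)

  # log-decrement from successive positive peaks for the initial damping
  ext <- which(diff(sign(diff(ww))) == -2) + 1L
  ext <- ext[ww[ext] > 0]
  z0 <- 0.005
  if (length(ext) >= 2L) {
    amp <- ww[ext]
    k <- length(ext) - 1L
    del <- log(amp[1L] / amp[length(amp)]) / k
    if (is.finite(del) && del > 0) z0 <- del / sqrt(4 * pi^2 + del^2)
  }
  z0 <- min(max(z0, 1e-5), 0.5)

  # amplitude/phase from the first fitted cycle
  cyc <- tt < 2 * pi / w_d0
  X0 <- max(abs(ww[cyc])) / w_d0
  phi0 <- atan2(ww[1L] / w_d0, if (n > 1) (ww[2L] - ww[1L]) / dt / (-w_d0^2) else 0)

  model_omega <- function(t, X, phi, zeta, w_d) {
    w_n <- w_d / sqrt(1 - zeta^2)
    X * exp(-zeta * w_n * t) *
      (w_d * cos(w_d * t + phi) - zeta * w_n * sin(w_d * t + phi))
  }
  run_lm <- function(phi_start) minpack.lm::nls.lm(
    par = list(X = X0, phi = phi_start, zeta = z0, w_d = w_d0),
    lower = c(X = 0, phi = -2 * pi, zeta = 0, w_d = w_d0 * 0.5),
    upper = c(X = Inf, phi = 2 * pi, zeta = 0.999, w_d = w_d0 * 1.5),
    fn = function(p) ww - model_omega(tt, p$X, p$phi, p$zeta, p$w_d),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  # multi-start over the phase: a quarter-turn error in the initial phase
  # can strand the optimizer at the degenerate X = 0 solution
  fit <- run_lm(phi0)
  signal_ss <- sum(ww^2)
  for (shift in c(pi / 2, pi, 3 * pi / 2)) {
    if (fit$info %in% 1:4 && stats::deviance(fit) < 0.25 * signal_ss &&
        stats::coef(fit)[["X"]] > 0) break
    cand <- run_lm(((phi0 + shift + 2 * pi) %% (4 * pi)) - 2 * pi)
    if (stats::deviance(cand) < stats::deviance(fit)) fit <- cand
  }
  if (!(fit$info %in% 1:4))
    stop("damped-oscillator fit did not converge: ", fit$message,
         call. = FALSE)
  p <- as.list(stats::coef(fit))
  res <- ww - model_omega(tt, p$X, p$phi, p$zeta, p$w_d)
  w_n <- p$w_d / sqrt(1 - p$zeta^2)
  structure(list(zeta = p$zeta, omega_n = w_n, omega_d = p$w_d,
                 X = p$X, phi = p$phi, tau = 2 * pi / p$w_d,
                 residual_rms = sqrt(mean(res^2)), residuals = res,
                 window = fit_window, n = n, fit = fit),
            class = "damped_fit")
}

#' @export
print.damped_fit <- function(x, ...) {
  cat("<damped_fit>\n")
  cat(sprintf("  omega_d  %.8g rad s^-1   (tau = %.8g s)\n", x$omega_d, x$tau))
  cat(sprintf("  zeta     %.4g    omega_n  %.8g rad s^-1\n", x$zeta, x$omega_n))
  cat(sprintf("  X        %.4g rad   phi  %.4g rad\n", x$X, x$phi))
  cat(sprintf("  residual RMS %.3g rad s^-1 over %d samples (%g s window)\n",
              x$residual_rms, x$n, x$window))
  invisible(x)
}

#' @export
coef.damped_fit <- function(object, ...)
  c(X = object$X, phi = object$phi, zeta = object$zeta,
    omega_d = object$omega_d, omega_n = object$omega_n, tau = object$tau)

#' @export
predict.damped_fit <- function(object, t, ...) {
  object$X * exp(-object$zeta * object$omega_n * t) *
    (object$omega_d * cos(object$omega_d * t + object$phi) -
       object$zeta * object$omega_n * sin(object$omega_d * t + object$phi))
}

#' @export
residuals.damped_fit <- function(object, ...) object$residuals

#' Aggregate repeated period measurements
#'
#' Unweighted mean of the per-fit periods across repeated measurements, with
#' the standard deviation attached.
#'
#' @param fits list of [fit_damped_oscillator()] results (or a single fit).
#' @return the mean period, s, with attributes `sd` and `n`.
#' @export
period_estimate <- function(fits) {
  if (inherits(fits, "damped_fit")) fits <- list(fits)
  if (!length(fits)) stop("insufficient data: no fits supplied", call. = FALSE)
  taus <- vapply(fits, `[[`, 0, "tau")
  structure(mean(taus), sd = stats::sd(taus), n = length(taus))
}

#' Trifilar rig moment of inertia from the oscillation period
#'
#' Small-angle single-degree-of-freedom trifilar formula
#' `I = m g R^2 tau^2 / (4 pi^2 L)`.
#'
#' @param m oscillating mass, kg.
#' @param g gravitational acceleration, m s^-2.
#' @param R thread radius from the rotation center, m.
#' @param tau oscillation period, s.
#' @param L mean thread length, m.
#' @return moment of inertia about the rotation axis, kg m^2.
#' @export
rig_moi <- function(m, g, R, tau, L) {
  args <- c(m = m, g = g, R = R, tau = tau, L = L)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all arguments must be strictly positive", call. = FALSE)
  m * g * R^2 * tau^2 / (4 * pi^2 * L)
}

#' Specimen MoI with CoM-misalignment correction
#'
#' Dorsoventral MoI of the specimen about its own CoM-through, board-normal
#' axis, from the loaded-pendulum period.  The combined system oscillates
#' about the rig's rotation axis, so the specimen contributes its CoM MoI
#' plus the parallel-axis term `m_b D^2` for the offset `D` between the
#' specimen CoM and the rig rotation axis:
#' \deqn{I_{dv} = \frac{(m_b + m_p)\, g R^2 \tau^2}{4\pi^2 L} - I_p - m_b D^2.}
#' At `D = 0` this reduces exactly to the uncorrected difference (combined
#' MoI via the trifilar formula with total mass, minus `I_p`).
#'
#' @param m_b specimen mass, kg.
#' @param m_p pendulum mass without specimen, kg (taken from `rig` if omitted).
#' @param I_p rig MoI without specimen, kg m^2 (taken from `rig` if omitted).
#' @param tau_with oscillation period with the specimen aboard, s.
#' @param rig a [pendulum_rig()] supplying `g`, `R`, `L` (and defaults for
#'   `m_p`, `I_p`).
#' @param D CoM offset between specimen and rig rotation axis, m (>= 0).
#' @return specimen MoI about its own CoM axis, kg m^2.
#' @export
specimen_moi_corrected <- function(m_b, m_p = rig$m_p, I_p = rig$I_p,
                                   tau_with, rig, D = 0) {
  stopifnot(inherits(rig, "pendulum_rig"))
  if (D < 0) stop("CoM offset D must be non-negative", call. = FALSE)
  if (tau_with <= 0) stop("tau_with must be positive", call. = FALSE)
  combined <- rig_moi(m_b + m_p, rig$g, rig$R, tau_with, rig$L)
  combined - I_p - m_b * D^2
}

#' Analytic cuboid (machined block) moment of inertia
#'
#' Closed form for a uniform rectangular block about a principal axis
#' through its CoM: `(m/12) * (sum of squared dimensions perpendicular to
#' the axis)`.  Machined blocks of known geometry serve as the physical
#' oracle for the pendulum measurement chain.
#'
#' @param dims length-3 numeric `(a, b, c)`, m.
#' @param mass kg.
#' @param axis which principal axis, 1-3 (axis `i` runs along `dims[i]`).
#' @return kg m^2.
#' @export
analytic_block_moi <- function(dims, mass, axis) {
  stopifnot(length(dims) == 3L, all(dims > 0), mass > 0, axis %in% 1:3)
  perp <- dims[-axis]
  mass / 12 * sum(perp^2)
}
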