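#' Simulate a stimulated dopamine trace under Michaelis-Menten kinetics
#'
#' Forward model for extracellular dopamine at the recording electrode:
#' \deqn{dC/dt = [DA]_p \sum_i \delta(t - t_i) - V_{max} C / (K_M + C)}
#' Each stimulation pulse adds `dap` uM instantaneously at its pulse time
#' (pulse width 4 ms is negligible at the 100 ms sampling interval), and
#' dopamine is cleared by saturable transporter uptake with maximal rate
#' `vmax` and fixed Michaelis constant `km`. Integration uses classical RK4
#' on a fine internal grid and reports on the acquisition grid.
#'
#' @param protocol A [stim_protocol()].
#' @param dap Dopamine released per pulse, uM (> 0).
#' @param vmax Maximal uptake rate, uM/s (>= 0).
#' @param km Michaelis constant, uM (default 0.160, the value the analysis
#'   holds fixed throughout).
#' @param duration_s Trace duration; must cover all pulse times. Default:
#'   last pulse + 9 s of clearance.
#' @param output_dt_s Acquisition interval (default 0.1 s).
#' @param internal_dt_s Internal RK4 step (default 1 ms).
#' @return A calibrated `fscv_trace` (uM) starting at t = 0 with C(0) = 0.
#' @examples
#' tr <- simulate_trace(stim_protocol(), dap = 1, vmax = 2)
#' peak_release(tr)
#' @export
simulate_trace <- function(protocol, dap, vmax, km = 0.160, duration_s = NULL,
                           output_dt_s = 0.1, internal_dt_s = 0.001) {
  stopifnot(inherits(protocol, "stim_protocol"))
  check_scalar(dap, "dap", lower = 0, strict_lower = TRUE)
  check_scalar(vmax, "vmax", lower = 0)
  check_scalar(km, "km", lower = 0, strict_lower = TRUE)
  check_scalar(output_dt_s, "output_dt_s", lower = 0, strict_lower = TRUE)
  check_scalar(internal_dt_s, "internal_dt_s", lower = 0, strict_lower = TRUE)
  pt <- pulse_times(protocol)
  if (is.null(duration_s)) duration_s <- max(pt) + 9
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (max(pt) > duration_s)
    stop("pulse times extend beyond the trace duration", call. = FALSE)
  times <- seq(0, duration_s, by = output_dt_s)
  values <- .mm_integrate(times, pt, dap, vmax, km, internal_dt_s)
  fscv_trace(times, values, units = "uM", protocol = protocol)
}

# Model evaluation on an arbitrary time grid (used by the fitter and predict).
mm_model_values <- function(times, protocol, dap, vmax, km, internal_dt_s) {
  .mm_integrate(times, pulse_times(protocol), dap, vmax, km, internal_dt_s)
}

#' Fit the Michaelis-Menten release/uptake model to a dopamine trace
#'
#' Estimates per-pulse release `[DA]_p` and maximal uptake rate `V_max` by
#' bounded Levenberg-Marquardt least squares, with the Michaelis constant held
#' fixed (default 0.160 uM). The fit is self-initializing: the starting
#' release is the baseline-subtracted observed peak divided by the pulse
#' count, and the starting `V_max` is the steepest falling-phase slope. The
#' pre-stimulus baseline mean is subtracted before fitting.
#'
#' @param trace A calibrated (`uM`) `fscv_trace`.
#' @param protocol The stimulation protocol; defaults to the trace's own.
#' @param km Fixed Michaelis constant, uM (never estimated).
#' @param internal_dt_s Internal integration step for model evaluation.
#' @return An object of class `kinetic_fit` with components `coefficients`
#'   (`dap`, `vmax`), `km`, `rss`, `converged`, `baseline`, `fitted`, and the
#'   input trace. Methods: `print`, `coef`, `fitted`, `residuals`, `predict`,
#'   `plot`.
#' @examples
#' tr <- simulate_trace(stim_protocol(), dap = 0.8, vmax = 2)
#' fit <- fit_kinetics(tr)
#' coef(fit)
#' @export
fit_kinetics <- function(trace, protocol = trace$protocol, km = 0.160,
                         internal_dt_s = 0.001) {
  stopifnot(inherits(trace, "fscv_trace"))
  if (trace$units != "uM")
    stop("fit_kinetics requires a calibrated trace in uM", call. = FALSE)
  check_scalar(km, "km", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(protocol, "stim_protocol"))

  onset <- protocol$onset_s
  pre <- trace$times < onset
  baseline <- if (any(pre)) mean(trace$values[pre]) else 0
  y <- trace$values - baseline
  peak <- max(y[trace$times >= onset])
  if (!is.finite(peak) || peak <= 0 || all(abs(y) < .Machine$double.eps))
    stop("no identifiable evoked release in this trace", call. = FALSE)

  dt <- trace$times[2] - trace$times[1]
  fall <- -diff(y) / dt
  vmax0 <- min(20, max(0.05, max(fall, na.rm = TRUE)))
  dap0 <- min(10, max(1e-3, peak / protocol$n_pulses))

  resid_fn <- function(p) {
    mm_model_values(trace$times, protocol, p[1], p[2], km, internal_dt_s) - y
  }
  fit <- minpack.lm::nls.lm(par = c(dap = dap0, vmax = vmax0), fn = resid_fn,
                            lower = c(1e-6, 0), upper = c(10, 20),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  fitted_vals <- mm_model_values(trace$times, protocol, est[1], est[2], km,
                                 internal_dt_s)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("kinetic fit did not converge: ", fit$message, call. = FALSE)
  structure(list(coefficients = c(dap = unname(est[1]), vmax = unname(est[2])),
                 km = km, rss = sum((fitted_vals - y)^2), converged = converged,
                 baseline = baseline, fitted = fitted_vals + baseline,
                 trace = trace, protocol = protocol,
                 internal_dt_s = internal_dt_s),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Michaelis-Menten kinetic fit\n")
  cat(sprintf("  [DA]p = %.4g uM/pulse, Vmax = %.4g uM/s (Km fixed at %.3g uM)\n",
              x$coefficients["dap"], x$coefficients["vmax"], x$km))
  cat(sprintf("  RSS = %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
fitted.kinetic_fit <- function(object, ...) object$fitted

#' @export
residuals.kinetic_fit <- function(object, ...) object$trace$values - object$fitted

#' @export
predict.kinetic_fit <- function(object, times = object$trace$times, ...) {
  mm_model_values(times, object$protocol, object$coefficients["dap"],
                  object$coefficients["vmax"], object$km,
                  object$internal_dt_s) + object$baseline
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  plot(x$trace, ...)
  graphics::lines(x$trace$times, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  r <- residuals(x$fit)
  cat(sprintf("  residual SD = %.4g uM over %d samples, baseline %.4g uM\n",
              stats::sd(r), length(r), x$fit$baseline))
  invisible(x)
}
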