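#' Stimulation protocol for an FSCV recording
#'
#' Describes the electrical stimulus delivered to the slice: number of pulses,
#' pulse frequency (for trains), amperage, pulse width and the time of the
#' first pulse on the recording clock.
#'
#' @param n_pulses Number of stimulation pulses (>= 1).
#' @param frequency_hz Pulse frequency in Hz; required when `n_pulses > 1`.
#' @param amplitude_uA Stimulation amperage in microamps.
#' @param pulse_width_ms Pulse width in milliseconds (informational; pulses are
#'   modelled as instantaneous since 4 ms is far below the 100 ms sampling
#'   interval).
#' @param onset_s Time of the first pulse, in seconds from trace start.
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol()                       # single 350 uA pulse at t = 1 s
#' stim_protocol(5, frequency_hz = 20)   # 5-pulse 20 Hz train
#' @export
stim_protocol <- function(n_pulses = 1, frequency_hz = NULL, amplitude_uA = 350,
                          pulse_width_ms = 4, onset_s = 1) {
  n_pulses <- check_count(n_pulses, "n_pulses", lower = 1L)
  check_scalar(amplitude_uA, "amplitude_uA", lower = 0, strict_lower = TRUE)
  check_scalar(pulse_width_ms, "pulse_width_ms", lower = 0, strict_lower = TRUE)
  check_scalar(onset_s, "onset_s", lower = 0)
  if (n_pulses > 1L) {
    if (is.null(frequency_hz))
      stop("'frequency_hz' is required for multi-pulse protocols", call. = FALSE)
    check_scalar(frequency_hz, "frequency_hz", lower = 0, strict_lower = TRUE)
  }
  structure(list(n_pulses = n_pulses,
                 frequency_hz = if (n_pulses > 1L) frequency_hz else NA_real_,
                 amplitude_uA = amplitude_uA, pulse_width_ms = pulse_width_ms,
                 onset_s = onset_s),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  if (x$n_pulses == 1L)
    cat(sprintf("Stimulus: 1 pulse, %g uA, %g ms, onset %g s\n",
                x$amplitude_uA, x$pulse_width_ms, x$onset_s))
  else
    cat(sprintf("Stimulus: %d pulses @ %g Hz, %g uA, %g ms, onset %g s\n",
                x$n_pulses, x$frequency_hz, x$amplitude_uA, x$pulse_width_ms,
                x$onset_s))
  invisible(x)
}

# Absolute pulse times implied by a protocol.
pulse_times <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$n_pulses == 1L) return(protocol$onset_s)
  protocol$onset_s + (seq_len(protocol$n_pulses) - 1L) / protocol$frequency_hz
}

#' Construct an FSCV concentration (or current) trace
#'
#' A trace is a uniformly sampled time series of dopamine concentration (uM
#' after calibration) or electrode current (nA before calibration), together
#' with the stimulation protocol that evoked it.
#'
#' @param times Sampling times in seconds, on a uniform strictly increasing
#'   grid (default acquisition interval 0.1 s).
#' @param values Measured values, same length as `times`; all finite.
#' @param units `"uM"` (calibrated concentration) or `"nA"` (raw current).
#' @param protocol A [stim_protocol()].
#' @return An object of class `fscv_trace`.
#' @export
fscv_trace <- function(times, values, units = c("uM", "nA"),
                       protocol = stim_protocol()) {
  units <- match.arg(units)
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) < 10L) stop("a trace needs at least 10 samples", call. = FALSE)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("trace times and values must be finite", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("trace times must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("trace times must lie on a uniform grid", call. = FALSE)
  stopifnot(inherits(protocol, "stim_protocol"))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 units = units, protocol = protocol),
            class = "fscv_trace")
}

#' @export
print.fscv_trace <- function(x, ...) {
  cat(sprintf("FSCV trace: %d samples, dt = %g s, units %s, peak %.3g %s\n",
              length(x$times), x$times[2] - x$times[1], x$units,
              max(x$values), x$units))
  print(x$protocol)
  invisible(x)
}

#' @export
as.data.frame.fscv_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' @export
plot.fscv_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = sprintf("dopamine (%s)", x$units), ...)
  graphics::abline(v = pulse_times(x$protocol), lty = 3, col = "grey50")
  invisible(x)
}

#' Electrode calibration record
#'
#' Post-experiment calibration of the carbon-fiber electrode against a known
#' dopamine standard (3 uM by default) in a flow-injection system. The
#' conversion factor is the peak current per unit concentration.
#'
#' @param standard_concentration_uM Concentration of the dopamine standard (uM).
#' @param peak_current_nA Peak current recorded for the standard (nA, > 0).
#' @return A `calibration_record` with derived `factor` in nA per uM.
#' @export
calibration_record <- function(standard_concentration_uM = 3, peak_current_nA) {
  check_scalar(standard_concentration_uM, "standard_concentration_uM",
               lower = 0, strict_lower = TRUE)
  check_scalar(peak_current_nA, "peak_current_nA", lower = 0, strict_lower = TRUE)
  structure(list(standard_concentration_uM = standard_concentration_uM,
                 peak_current_nA = peak_current_nA,
                 factor = peak_current_nA / standard_concentration_uM),
            class = "calibration_record")
}

#' Convert a raw current trace to dopamine concentration
#'
#' Divides the recorded current by the electrode's calibration factor
#' (nA per uM), converting nA to uM. Shape and sampling are preserved.
#'
#' @param trace An `fscv_trace` in nA.
#' @param cal A [calibration_record()].
#' @return The trace in uM.
#' @export
calibrate <- function(trace, cal) {
  stopifnot(inherits(trace, "fscv_trace"), inherits(cal, "calibration_record"))
  if (trace$units != "nA")
    stop("trace is already calibrated (units uM)", call. = FALSE)
  if (!is.finite(cal$factor) || cal$factor <= 0)
    stop("calibration factor must be positive", call. = FALSE)
  fscv_trace(trace$times, trace$values / cal$factor, units = "uM",
             protocol = trace$protocol)
}

#' Evoked peak dopamine release of a trace
#'
#' The maximum value after stimulus onset minus the pre-stimulus baseline mean,
#' floored at zero (a trace with no post-stimulus rise has zero evoked
#' release).
#'
#' @param trace An `fscv_trace`.
#' @return Peak evoked release in the trace's units.
#' @export
peak_release <- function(trace) {
  stopifnot(inherits(trace, "fscv_trace"))
  onset <- trace$protocol$onset_s
  post <- trace$times >= onset
  if (!any(post))
    stop("stimulus onset lies at or beyond the end of the trace", call. = FALSE)
  baseline <- if (any(!post)) mean(trace$values[!post]) else 0
  max(0, max(trace$values[post]) - baseline)
}

#' Baseline stability check
#'
#' A baseline is considered established when the last `k` collections vary by
#' no more than `tol` of their mean, i.e. `(max - min) / mean <= tol`.
#'
#' @param peaks Numeric vector of successive peak values; at least `k` needed.
#' @param k Number of trailing collections to assess (default 3).
#' @param tol Relative variability tolerance (default 0.10).
#' @return `TRUE` if stable.
#' @export
is_stable <- function(peaks, k = 3, tol = 0.10) {
  k <- check_count(k, "k", lower = 2L)
  check_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  stopifnot(is.numeric(peaks))
  if (length(peaks) < k)
    stop(sprintf("need at least %d peaks, got %d", k, length(peaks)), call. = FALSE)
  last <- utils::tail(peaks, k)
  m <- mean(last)
  if (m <= 0) stop("mean of trailing peaks must be positive", call. = FALSE)
  (max(last) - min(last)) / m <= tol
}

#' Write / read a trace as CSV with a JSON sidecar
#'
#' The CSV holds columns `time_s,value`; the sidecar `<path>.json` carries
#' units and the stimulation protocol so a trace round-trips losslessly.
#'
#' @param trace An `fscv_trace`.
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   reconstructed `fscv_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fscv_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(units = trace$units,
               protocol = unclass(trace$protocol))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pr <- meta$protocol
  proto <- stim_protocol(n_pulses = pr$n_pulses,
                         frequency_hz = if (pr$n_pulses > 1) pr$frequency_hz else NULL,
                         amplitude_uA = pr$amplitude_uA,
                         pulse_width_ms = pr$pulse_width_ms,
                         onset_s = pr$onset_s)
  fscv_trace(df$time_s, df$value, units = meta$units, protocol = proto)
}
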