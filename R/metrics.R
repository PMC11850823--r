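#' Fit a four-parameter sigmoid to an input-output series
#'
#' Single-pulse peak dopamine release as a function of stimulation amperage is
#' summarised by a four-parameter logistic in linear amperage:
#' \deqn{y = bottom + (top - bottom) / (1 + \exp((EA_{50} - I)/steepness))}
#' so that the fitted response at `I = ea50` is exactly the midpoint
#' `(top + bottom)/2`. `EA50` is the half-maximal excitatory amperage and the
#' span (`top - bottom`) is the dynamic range of evoked release.
#'
#' @param amplitudes Stimulation amperages, uA; at least 5 distinct values.
#' @param responses Peak evoked release at each amperage (same length, >= 0
#'   up to noise).
#' @return An object of class `io_sigmoid` with `coefficients`
#'   (`bottom`, `top`, `ea50`, `steepness`), `span`, `rss`, `fitted`, and the
#'   data. Methods: `print`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' a <- c(50, 100, 200, 300, 400, 500, 600, 750, 900)
#' y <- 1 / (1 + exp((316 - a) / 80))
#' fit <- fit_io_sigmoid(a, y)
#' coef(fit)
#' @export
fit_io_sigmoid <- function(amplitudes, responses) {
  stopifnot(is.numeric(amplitudes), is.numeric(responses),
            length(amplitudes) == length(responses))
  if (length(unique(amplitudes)) < 5L)
    stop("need at least 5 distinct amplitudes for a 4-parameter fit", call. = FALSE)
  if (!all(is.finite(amplitudes)) || !all(is.finite(responses)))
    stop("amplitudes and responses must be finite", call. = FALSE)
  if (stats::sd(responses) == 0)
    stop("responses are constant; sigmoid parameters are not identifiable",
         call. = FALSE)

  amplitudes <- unname(amplitudes)
  responses <- unname(responses)
  bottom0 <- min(responses)
  top0 <- max(responses)
  mid <- (bottom0 + top0) / 2
  ea500 <- amplitudes[which.min(abs(responses - mid))]
  steep0 <- diff(range(amplitudes)) / 5

  fn <- function(p) {
    z <- pmin(700, pmax(-700, (p["ea50"] - amplitudes) / p["steepness"]))
    p["bottom"] + (p["top"] - p["bottom"]) / (1 + exp(z)) - responses
  }
  fit <- minpack.lm::nls.lm(
    par = c(bottom = bottom0, top = top0, ea50 = ea500, steepness = steep0),
    fn = fn,
    lower = c(-Inf, -Inf, min(amplitudes) * 0.1, 1e-3),
    upper = c(Inf, Inf, max(amplitudes) * 10, diff(range(amplitudes)) * 10),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000))
  p <- fit$par
  if (!(fit$info %in% 1:4))
    warning("sigmoid fit did not converge: ", fit$message, call. = FALSE)
  if (p["top"] < p["bottom"])
    warning("fitted top plateau is below the bottom plateau; the series does ",
            "not look like an ascending input-output curve", call. = FALSE)
  guard <- c(min(amplitudes) * 0.5, max(amplitudes) * 2)
  if (p["ea50"] < guard[1] || p["ea50"] > guard[2])
    warning(sprintf("EA50 (%.3g uA) falls outside the tested amperage range guard band [%g, %g]",
                    p["ea50"], guard[1], guard[2]), call. = FALSE)
  fitted_vals <- fn(p) + responses
  structure(list(coefficients = c(bottom = unname(p["bottom"]),
                                  top = unname(p["top"]),
                                  ea50 = unname(p["ea50"]),
                                  steepness = unname(p["steepness"])),
                 span = unname(p["top"] - p["bottom"]),
                 rss = sum((fitted_vals - responses)^2),
                 converged = fit$info %in% 1:4,
                 amplitudes = amplitudes, responses = responses,
                 fitted = fitted_vals),
            class = "io_sigmoid")
}

#' @export
print.io_sigmoid <- function(x, ...) {
  cat("Four-parameter input-output sigmoid\n")
  cat(sprintf("  bottom = %.4g, top = %.4g, EA50 = %.4g uA, steepness = %.4g uA\n",
              x$coefficients["bottom"], x$coefficients["top"],
              x$coefficients["ea50"], x$coefficients["steepness"]))
  cat(sprintf("  span = %.4g, RSS = %.4g\n", x$span, x$rss))
  invisible(x)
}

#' @export
coef.io_sigmoid <- function(object, ...) object$coefficients

#' @export
fitted.io_sigmoid <- function(object, ...) object$fitted

#' @export
residuals.io_sigmoid <- function(object, ...) object$responses - object$fitted

#' @export
predict.io_sigmoid <- function(object, amplitudes = object$amplitudes, ...) {
  p <- object$coefficients
  p["bottom"] + (p["top"] - p["bottom"]) /
    (1 + exp((p["ea50"] - amplitudes) / p["steepness"]))
}

#' @export
plot.io_sigmoid <- function(x, ...) {
  graphics::plot(x$amplitudes, x$responses, xlab = "amperage (uA)",
                 ylab = "peak release", ...)
  grid_a <- seq(min(x$amplitudes), max(x$amplitudes), length.out = 200)
  graphics::lines(grid_a, predict(x, grid_a), col = "red3", lwd = 2)
  graphics::abline(v = x$coefficients["ea50"], lty = 3)
  invisible(x)
}

#' Span (dynamic range) of an input-output sigmoid
#'
#' Upper plateau minus lower plateau of the fitted curve.
#'
#' @param fit An `io_sigmoid` fit.
#' @return `top - bottom` in response units.
#' @export
span <- function(fit) UseMethod("span")

#' @export
span.io_sigmoid <- function(fit) fit$span

#' Normalize a frequency-response series to single-pulse release
#'
#' Multi-pulse (5-pulse train) peak release at each stimulation frequency is
#' expressed relative to the subject's single-pulse peak.
#'
#' @param frequencies Stimulation frequencies in Hz, strictly increasing.
#' @param peaks Peak release at each frequency (same units as
#'   `single_pulse_peak`).
#' @param single_pulse_peak Single-pulse peak release (> 0).
#' @param condition `"pre"` or `"post"` drug, carried as metadata.
#' @return A `frequency_series` data frame with columns `frequency_hz` and
#'   `normalized_response`, plus a `condition` attribute.
#' @export
normalize_frequency_series <- function(frequencies, peaks, single_pulse_peak,
                                       condition = c("pre", "post")) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(frequencies), is.numeric(peaks),
            length(frequencies) == length(peaks))
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing", call. = FALSE)
  check_scalar(single_pulse_peak, "single_pulse_peak", lower = 0,
               strict_lower = TRUE)
  if (any(peaks < 0)) stop("peaks must be non-negative", call. = FALSE)
  out <- data.frame(frequency_hz = frequencies,
                    normalized_response = peaks / single_pulse_peak)
  attr(out, "condition") <- condition
  class(out) <- c("frequency_series", "data.frame")
  out
}

#' Area under a frequency-response curve
#'
#' Trapezoidal integral of the (normalized) response over the linear Hz axis,
#' on the observed frequency grid without interpolation.
#'
#' @param series A `frequency_series`, or a data frame with columns
#'   `frequency_hz` and `normalized_response`.
#' @return AUC in response x Hz units.
#' @export
auc_frequency <- function(series) {
  f <- series$frequency_hz
  y <- series$normalized_response
  stopifnot(is.numeric(f), is.numeric(y), length(f) == length(y))
  if (length(f) < 2L)
    stop("AUC needs at least 2 frequencies", call. = FALSE)
  if (any(diff(f) <= 0)) stop("frequencies must be strictly increasing", call. = FALSE)
  sum(diff(f) * (y[-1] + y[-length(y)]) / 2)
}

#' Post-drug response as a percentage of the pre-drug baseline
#'
#' @param pre_peak Pre-drug baseline peak (> 0).
#' @param post_peak Post-drug peak (>= 0).
#' @return `100 * post_peak / pre_peak` (percent of baseline); inhibition is
#'   `100` minus this value.
#' @export
percent_baseline <- function(pre_peak, post_peak) {
  check_scalar(pre_peak, "pre_peak", lower = 0, strict_lower = TRUE)
  check_scalar(post_peak, "post_peak", lower = 0)
  100 * post_peak / pre_peak
}

#' Kappa opioid receptor sensitivity and efficacy metrics
#'
#' With the agonist applied cumulatively (0.3 uM then 1 uM), both inhibition
#' percentages are referenced to the original pre-drug baseline: potency is
#' the percent inhibition of evoked release at the moderate concentration
#' (300 nM) and efficacy the percent inhibition at the saturating
#' concentration (1 uM). Peaks at each stage should already be stabilized
#' (see [is_stable()]); multiple collections are averaged.
#'
#' @param baseline_peaks Stabilized pre-drug peak(s).
#' @param peaks_300nM Stabilized peak(s) in 300 nM agonist.
#' @param peaks_1uM Stabilized peak(s) in 1 uM agonist.
#' @return A list with `percent_baseline_300nM`, `percent_baseline_1uM`,
#'   `potency_300nM` and `efficacy_1uM` (all percentages).
#' @export
kor_sensitivity_metrics <- function(baseline_peaks, peaks_300nM, peaks_1uM) {
  if (missing(peaks_300nM) || missing(peaks_1uM) ||
      length(peaks_300nM) == 0L || length(peaks_1uM) == 0L)
    stop("both dose levels (300 nM and 1 uM) are required", call. = FALSE)
  pre <- mean(baseline_peaks)
  pb300 <- percent_baseline(pre, mean(peaks_300nM))
  pb1000 <- percent_baseline(pre, mean(peaks_1uM))
  list(percent_baseline_300nM = pb300,
       percent_baseline_1uM = pb1000,
       potency_300nM = 100 - pb300,
       efficacy_1uM = 100 - pb1000)
}

#' Percent change in frequency-curve AUC (dynorphin release-probability proxy)
#'
#' Percent change between the pre- and post-antagonist AUCs of the normalized
#' frequency-response curve.
#'
#' @param auc_pre Pre-drug AUC (> 0).
#' @param auc_post Post-drug AUC.
#' @return `100 * (auc_post - auc_pre) / auc_pre`.
#' @export
disinhibition_auc_change <- function(auc_pre, auc_post) {
  check_scalar(auc_pre, "auc_pre", lower = 0, strict_lower = TRUE)
  check_scalar(auc_post, "auc_post", lower = 0)
  100 * (auc_post - auc_pre) / auc_pre
}
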