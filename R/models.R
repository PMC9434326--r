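#' Oscillator parameter bundle
#'
#' Constructs and validates the parameter set of the amplitude-changing
#' circadian oscillator
#' \deqn{y(t) = A \, e^{-\gamma t / 2} \cos(2\pi t/\tau + \phi) + y_0,}
#' where `amplitude` (\eqn{A}, expression z-units) is the initial amplitude at
#' \eqn{t = 0}, `ac_coef` (\eqn{\gamma}, 1/h) is the amplitude-change (AC)
#' coefficient of the exponential envelope (positive = damped, negative =
#' forced), `period` (\eqn{\tau}, h) the oscillation period, `phase`
#' (\eqn{\phi}, radians) the phase shift, and `baseline` (\eqn{y_0}) the
#' midline. The amplitude is kept non-negative; a negative input amplitude is
#' folded into the phase, and the phase is normalized to \eqn{[0, 2\pi)}.
#'
#' @param amplitude Initial amplitude (z-units), any finite value; negative
#'   values are absorbed into the phase.
#' @param ac_coef AC coefficient \eqn{\gamma} (1/h).
#' @param period Oscillation period \eqn{\tau} (h), must be positive.
#' @param phase Phase shift \eqn{\phi} (radians).
#' @param baseline Midline expression \eqn{y_0} (z-units).
#'
#' @return An object of class `echo_params`: a named list with elements
#'   `amplitude`, `ac_coef`, `period`, `phase`, `baseline`.
#' @examples
#' p <- echo_params(amplitude = 1, ac_coef = 0.1, period = 24, phase = 0)
#' echo_curve(seq(0, 48, by = 2), p)
#' @export
echo_params <- function(amplitude, ac_coef, period, phase, baseline = 0) {
  vals <- c(amplitude, ac_coef, period, phase, baseline)
  if (length(vals) != 5 || !all(is.finite(vals))) {
    abort("all oscillator parameters must be single finite numbers",
          class = "circatrend_invalid_parameter")
  }
  if (period <= 0) {
    abort("`period` must be positive", class = "circatrend_invalid_parameter")
  }
  if (amplitude < 0) {
    amplitude <- -amplitude
    phase <- phase + pi
  }
  structure(
    list(amplitude = amplitude, ac_coef = ac_coef, period = period,
         phase = phase %% (2 * pi), baseline = baseline),
    class = "echo_params"
  )
}

#' @export
print.echo_params <- function(x, ...) {
  cat(sprintf(
    "<echo_params> A = %.4g, gamma = %.4g /h, tau = %.4g h, phi = %.4g rad, y0 = %.4g\n",
    x$amplitude, x$ac_coef, x$period, x$phase, x$baseline))
  invisible(x)
}

#' Evaluate the amplitude-changing oscillator
#'
#' Computes \eqn{y(t) = A e^{-\gamma t/2} \cos(2\pi t/\tau + \phi) + y_0} at
#' the given times.
#'
#' @param times Numeric vector of times (h), finite and non-negative.
#' @param params An [echo_params()] object (or a named list with the same
#'   fields).
#' @return Numeric vector of expression values, one per time.
#' @examples
#' echo_curve(0:24, echo_params(1, 0, 24, 0))
#' @export
echo_curve <- function(times, params) {
  check_times(times)
  p <- as_echo_params(params)
  p$amplitude * exp(-p$ac_coef * times / 2) *
    cos(2 * pi * times / p$period + p$phase) + p$baseline
}

as_echo_params <- function(params) {
  if (inherits(params, "echo_params")) return(params)
  need <- c("amplitude", "ac_coef", "period", "phase")
  if (!all(need %in% names(params))) {
    abort("`params` must carry amplitude, ac_coef, period, phase (+ baseline)",
          class = "circatrend_invalid_parameter")
  }
  echo_params(params$amplitude, params$ac_coef, params$period, params$phase,
              if (is.null(params$baseline)) 0 else params$baseline)
}

check_times <- function(times) {
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times)) ||
      any(times < 0)) {
    abort("`times` must be finite and non-negative",
          class = "circatrend_invalid_parameter")
  }
  invisible(times)
}

#' Trend-model parameter bundle
#'
#' A tagged union over the trend-model library: `"linear"` (`slope`,
#' `intercept`), `"exponential"` (`scale`, `rate`, `offset`:
#' \eqn{a e^{kt} + c}), `"echo"` (an [echo_params()] set), and
#' `"echo_linear"` (an [echo_params()] set plus `slope`).
#'
#' @param type One of `"linear"`, `"exponential"`, `"echo"`, `"echo_linear"`.
#' @param ... Numeric fields of the chosen variant (see Details).
#' @return An object of class `trend_params` with a `type` field.
#' @examples
#' trend_params("linear", slope = 0.5, intercept = 1)
#' trend_params("echo_linear", amplitude = 1, ac_coef = 0, period = 24,
#'              phase = 0, baseline = 0, slope = 0.5)
#' @export
trend_params <- function(type = c("linear", "exponential", "echo",
                                  "echo_linear"), ...) {
  type <- match.arg(type)
  fields <- list(...)
  need <- switch(type,
    linear = c("slope", "intercept"),
    exponential = c("scale", "rate", "offset"),
    echo = c("amplitude", "ac_coef", "period", "phase", "baseline"),
    echo_linear = c("amplitude", "ac_coef", "period", "phase", "baseline",
                    "slope"))
  missing_f <- setdiff(need, names(fields))
  if (length(missing_f)) {
    abort(paste0("missing fields for '", type, "' trend: ",
                 paste(missing_f, collapse = ", ")),
          class = "circatrend_invalid_parameter")
  }
  fields <- fields[need]
  if (!all(vapply(fields, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1)))) {
    abort("all trend parameters must be single finite numbers",
          class = "circatrend_invalid_parameter")
  }
  structure(c(list(type = type), fields), class = "trend_params")
}

#' Evaluate a trend model
#'
#' @param times Numeric vector of times (h), finite and non-negative.
#' @param params A [trend_params()] object.
#' @return Numeric vector of values, one per time.
#' @examples
#' trend_curve(0:10, trend_params("exponential", scale = 1, rate = 0.1,
#'                                offset = 0))
#' @export
trend_curve <- function(times, params) {
  check_times(times)
  if (!inherits(params, "trend_params")) {
    abort("`params` must be a trend_params object",
          class = "circatrend_invalid_parameter")
  }
  switch(params$type,
    linear = params$slope * times + params$intercept,
    exponential = params$scale * exp(params$rate * times) + params$offset,
    echo = echo_curve(times, params),
    echo_linear = echo_curve(times, params) + params$slope * times)
}

#' Classify the amplitude-change coefficient
#'
#' Assigns the AC category from the AC coefficient \eqn{\gamma}:
#' `harmonic` when \eqn{|\gamma| \le} `harmonic_cutoff`; `damped` (shrinking
#' amplitude) when `harmonic_cutoff` \eqn{< \gamma <} `extreme_cutoff`;
#' `forced` (growing amplitude) for the mirrored negative band; `repressed`
#' and `overexpressed` beyond \eqn{\pm}`extreme_cutoff`. Boundary values fall
#' into the milder category. The extreme categories describe essentially
#' monotone decay/growth rather than usable oscillations and are excluded
#' from circadian calls downstream (see [postrun_restrict()]).
#'
#' @param ac_coef Numeric vector of AC coefficients (1/h), finite.
#' @param harmonic_cutoff Half-width of the harmonic band (1/h); default 0.15.
#' @param extreme_cutoff Bound beyond which oscillation is treated as
#'   overexpression/repression (1/h); default 1.
#' @return Factor with levels `forced`, `harmonic`, `damped`,
#'   `overexpressed`, `repressed`.
#' @examples
#' classify_ac(c(-0.5, 0, 0.5, 2, -2))
#' @export
classify_ac <- function(ac_coef, harmonic_cutoff = 0.15, extreme_cutoff = 1) {
  if (!is.numeric(ac_coef) || anyNA(ac_coef) || any(!is.finite(ac_coef))) {
    abort("`ac_coef` must be finite", class = "circatrend_invalid_parameter")
  }
  if (!(harmonic_cutoff > 0 && harmonic_cutoff < extreme_cutoff)) {
    abort("need 0 < harmonic_cutoff < extreme_cutoff",
          class = "circatrend_invalid_parameter")
  }
  out <- ifelse(abs(ac_coef) <= harmonic_cutoff, "harmonic",
         ifelse(ac_coef > harmonic_cutoff & ac_coef < extreme_cutoff, "damped",
         ifelse(ac_coef < -harmonic_cutoff & ac_coef > -extreme_cutoff,
                "forced",
         ifelse(ac_coef >= extreme_cutoff, "repressed", "overexpressed"))))
  factor(out, levels = ac_categories())
}

#' AC category levels
#'
#' @param circadian_only If `TRUE`, return only the three categories counted
#'   as circadian oscillations (`forced`, `harmonic`, `damped`).
#' @return Character vector of category names.
#' @export
ac_categories <- function(circadian_only = FALSE) {
  core <- c("forced", "harmonic", "damped")
  if (circadian_only) core else c(core, "overexpressed", "repressed")
}

#' First peak time of an oscillator
#'
#' The smallest \eqn{t \ge 0} at which the cosine term reaches its maximum,
#' \eqn{((-\phi) \bmod 2\pi) \cdot \tau / (2\pi)} hours. The decaying/growing
#' envelope shifts the literal maximum of the damped curve slightly; the
#' conventional phase-derived peak is reported as it tracks the oscillation's
#' timing rather than its envelope.
#'
#' @param params An [echo_params()] object with positive amplitude.
#' @return Peak time in hours.
#' @examples
#' peak_time(echo_params(1, 0, 24, pi)) # 12
#' @export
peak_time <- function(params) {
  p <- as_echo_params(params)
  if (p$amplitude <= 0) {
    abort("peak time is undefined for zero amplitude",
          class = "circatrend_undefined_peak")
  }
  ((-p$phase) %% (2 * pi)) * p$period / (2 * pi)
}
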