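## Multi-start nonlinear least-squares fitting of the amplitude-changing
## oscillator. The start grid is deterministic: candidate periods at fixed
## steps across the period bounds crossed with equispaced phases, each grid
## point scored by the residual sum of squares of the best linear
## (amplitude, baseline) completion; the top distinct periods seed
## Levenberg-Marquardt refinement of all five parameters.

echo_grid <- function(times, period_bounds, period_step = 2, n_phases = 8) {
  taus <- seq(period_bounds[1], period_bounds[2], by = period_step)
  if (taus[length(taus)] < period_bounds[2]) taus <- c(taus, period_bounds[2])
  phis <- seq(0, 2 * pi, length.out = n_phases + 1)[seq_len(n_phases)]
  pts <- expand.grid(phi = phis, tau = taus)
  Q <- matrix(0, length(times), 2 * nrow(pts))
  for (j in seq_len(nrow(pts))) {
    X <- cbind(cos(2 * pi * times / pts$tau[j] + pts$phi[j]), 1)
    Q[, (2 * j - 1):(2 * j)] <- qr.Q(qr(X))
  }
  list(points = pts, Q = Q)
}

## grid RSS for every feature at once: one crossproduct, then per-point sums
grid_rss <- function(grid, vals) {
  cc <- crossprod(grid$Q, t(vals))^2 # (2G) x F
  g <- nrow(grid$points)
  proj <- cc[seq(1, 2 * g, by = 2), , drop = FALSE] +
    cc[seq(2, 2 * g, by = 2), , drop = FALSE]
  sweep(-proj, 2, rowSums(vals^2), "+") # G x F
}

refine_echo <- function(y, times, starts, period_bounds, ac_max) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-g * tt / 2) * cos(2 * pi * tt / tau + phi) + y0,
        data = data.frame(y = y, tt = times),
        start = list(A = s$A, g = s$g, tau = s$tau, phi = s$phi, y0 = s$y0),
        lower = c(A = 0, g = -ac_max, tau = period_bounds[1],
                  phi = -2 * pi, y0 = -Inf),
        upper = c(A = Inf, g = ac_max, tau = period_bounds[2],
                  phi = 4 * pi, y0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 120)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(rss = rss, A = cf[["A"]], g = cf[["g"]], tau = cf[["tau"]],
                   phi = cf[["phi"]], y0 = cf[["y0"]], converged = TRUE)
    }
  }
  best
}

## starts: list of grid rows (tau, phi) -> linear completion for (A, y0)
grid_start <- function(y, times, tau, phi) {
  X <- cbind(cos(2 * pi * times / tau + phi), 1)
  cf <- unname(qr.coef(qr(X), y))
  list(A = abs(cf[1]), g = 0, tau = tau,
       phi = if (cf[1] >= 0) phi else phi + pi, y0 = cf[2])
}

fit_echo_series <- function(y, times, grid, period_bounds, rss_g = NULL,
                            n_starts = 3, ac_max = 2) {
  n <- length(y)
  ss0 <- sum((y - mean(y))^2)
  flat <- list(model = "echo", amplitude = 0, ac_coef = 0,
               period = mean(period_bounds), phase = 0, baseline = mean(y),
               rss = ss0, n_obs = n, converged = TRUE)
  if (ss0 < n * 1e-20) return(flat)
  if (is.null(rss_g)) rss_g <- grid_rss(grid, matrix(y, nrow = 1))[, 1]
  ord <- order(rss_g)
  starts <- list(); taus_seen <- numeric()
  for (j in ord) {
    tau <- grid$points$tau[j]
    if (tau %in% taus_seen) next
    taus_seen <- c(taus_seen, tau)
    starts[[length(starts) + 1]] <-
      grid_start(y, times, tau, grid$points$phi[j])
    if (length(starts) >= n_starts) break
  }
  best <- refine_echo(y, times, starts, period_bounds, ac_max)
  if (is.null(best)) { # no start converged: report best grid evaluation
    s <- starts[[1]]
    res <- y - echo_curve(times, list(amplitude = s$A, ac_coef = 0,
                                      period = s$tau, phase = s$phi,
                                      baseline = s$y0))
    return(list(model = "echo", amplitude = s$A, ac_coef = 0, period = s$tau,
                phase = s$phi %% (2 * pi), baseline = s$y0,
                rss = sum(res^2), n_obs = n, converged = FALSE))
  }
  phi <- best$phi
  A <- best$A
  if (A < 0) { A <- -A; phi <- phi + pi }
  list(model = "echo", amplitude = A, ac_coef = best$g, period = best$tau,
       phase = phi %% (2 * pi), baseline = best$y0, rss = best$rss,
       n_obs = n, converged = best$converged)
}

#' Nested F-test for an oscillation fit
#'
#' Tests a fitted model against the intercept-only null:
#' \deqn{F = \frac{(RSS_0 - RSS_1)/(k-1)}{RSS_1/(n-k)},}
#' with `k` free model parameters and `n` observations; the p-value is the
#' upper tail of the F distribution with \eqn{(k-1, n-k)} degrees of
#' freedom. A model no better than the mean gives \eqn{F \le 0}, p = 1; a
#' perfect fit gives p = 0.
#'
#' @param rss0 Residual sum of squares of the intercept-only model.
#' @param rss1 Residual sum of squares of the fitted model.
#' @param n_obs Number of observations.
#' @param k Number of free model parameters (5 for the plain oscillator).
#'   Non-integer values are allowed (effective degrees of freedom).
#' @return The p-value.
#' @examples
#' oscillation_f_test(10, 5, 75, 5)
#' @export
oscillation_f_test <- function(rss0, rss1, n_obs, k) {
  if (n_obs <= k) {
    abort("F-test undefined: n_obs must exceed parameter count k",
          class = "circatrend_undefined_test")
  }
  if (rss0 <= n_obs * 1e-20) return(1) # nothing beyond the mean to explain
  if (rss1 <= max(1e-300, rss0 * 1e-14)) return(0)
  f <- ((rss0 - rss1) / (k - 1)) / (rss1 / (n_obs - k))
  if (!is.finite(f) || f <= 0) return(1)
  pf(f, k - 1, n_obs - k, lower.tail = FALSE)
}

## correlation-based alternative significance (Kendall tau between fitted
## curve and observations), selectable via significance = "kendall"
kendall_test <- function(fitted, y) {
  if (sd(fitted) == 0 || sd(y) == 0) return(1)
  stats::cor.test(fitted, y, method = "kendall",
                  alternative = "greater", exact = FALSE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values
#' (\eqn{q_i = \min_{p_{(j)} \ge p_{(i)}} m\, p_{(j)}/j}, capped at 1),
#' preserving input order. Thin validated wrapper around
#' `p.adjust(method = "BH")` so every module shares one code path.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1]", class = "circatrend_invalid_input")
  }
  p.adjust(p, method = "BH")
}

#' Fit the oscillator model to one series
#'
#' Fits \eqn{y(t) = A e^{-\gamma t/2} \cos(2\pi t/\tau + \phi) + y_0} by
#' deterministic multi-start nonlinear least squares. All replicate points
#' are fitted simultaneously at their timepoints; nothing is averaged.
#'
#' @param values Numeric vector of (preprocessed, complete) observations.
#' @param times Matching vector of times (h).
#' @param period_bounds Free-run period search bounds (h); defaults to
#'   `c(2 * min spacing, time span)`.
#' @param n_starts Number of distinct-period starts refined by
#'   Levenberg-Marquardt (default 3).
#' @param period_step,n_phases Start-grid resolution: candidate periods at
#'   `period_step`-h steps crossed with `n_phases` equispaced phases.
#' @param ac_max Box bound on \eqn{|\gamma|} during optimization (1/h).
#' @param significance `"ftest"` (nested F-test, default) or `"kendall"`
#'   (correlation of fitted curve with observations).
#' @return One-row tibble with the fitted parameters, `rss`, `rmse`,
#'   `n_obs`, `p_value`, `ac_category` and `converged`.
#' @examples
#' t <- rep(seq(0, 48, 2), each = 3)
#' y <- echo_curve(t, echo_params(1, 0.1, 24, 1))
#' fit_echo(y, t)
#' @export
fit_echo <- function(values, times, period_bounds = NULL, n_starts = 3,
                     period_step = 2, n_phases = 8, ac_max = 2,
                     significance = c("ftest", "kendall")) {
  significance <- match.arg(significance)
  if (length(values) != length(times) || anyNA(values)) {
    abort("`values` must be complete and match `times`",
          class = "circatrend_invalid_input")
  }
  period_bounds <- default_period_bounds(times, period_bounds)
  grid <- echo_grid(times, period_bounds, period_step, n_phases)
  fit <- fit_echo_series(values, times, grid, period_bounds,
                         n_starts = n_starts, ac_max = ac_max)
  fit_row(fit, values, times, "series", significance)
}

default_period_bounds <- function(times, period_bounds) {
  if (!is.null(period_bounds)) {
    if (length(period_bounds) != 2 || period_bounds[1] <= 0 ||
        period_bounds[1] >= period_bounds[2]) {
      abort("`period_bounds` must be increasing and positive",
            class = "circatrend_invalid_parameter")
    }
    return(period_bounds)
  }
  tps <- sort(unique(times))
  c(2 * min(diff(tps)), max(tps) - min(tps))
}

fit_row <- function(fit, y, times, feature_id, significance) {
  n <- fit$n_obs
  rss0 <- sum((y - mean(y))^2)
  k <- if (fit$model == "echo_linear") 6 else 5
  p <- if (significance == "kendall") {
    fitted <- echo_curve(times, fit) +
      if (fit$model == "echo_linear") fit$slope * times else 0
    kendall_test(fitted, y)
  } else {
    oscillation_f_test(rss0, fit$rss, n, k)
  }
  tibble::tibble(
    feature_id = feature_id,
    model = fit$model,
    period_h = fit$period,
    phase_rad = fit$phase,
    peak_time_h = if (fit$amplitude > 0) {
      ((-fit$phase) %% (2 * pi)) * fit$period / (2 * pi)
    } else NA_real_,
    amplitude = fit$amplitude,
    ac_coefficient = fit$ac_coef,
    ac_category = as.character(classify_ac(fit$ac_coef)),
    baseline = fit$baseline,
    slope = if (is.null(fit$slope)) NA_real_ else fit$slope,
    rss = fit$rss,
    rmse = sqrt(fit$rss / n),
    n_obs = n,
    p_value = p,
    converged = fit$converged
  )
}

#' Fit the oscillator model to every feature of a matrix
#'
#' Free-run multi-start oscillator fitting of each feature, followed by
#' nested F-tests and Benjamini-Hochberg adjustment across features. The
#' grid search over candidate periods is vectorized across all features;
#' results are deterministic for a given matrix and grid.
#'
#' @param df Complete wide expression tibble (run [preprocess()] first if
#'   the data contain missing values or need conditioning).
#' @inheritParams fit_echo
#' @return An object of class `echo_fit`. Use [tidy()] for the per-feature
#'   results tibble, [glance()] for a one-row summary, [autoplot()] to plot
#'   fitted curves, and [postrun_restrict()] to apply the circadian window.
#' @examples
#' sim <- simulate_dataset(sim_spec(n_features = c(harmonic = 3)), seed = 1)
#' fit <- fit_rhythms(preprocess(sim$rna))
#' tidy(fit)
#' @export
fit_rhythms <- function(df, period_bounds = NULL, n_starts = 3,
                        period_step = 2, n_phases = 8, ac_max = 2,
                        significance = c("ftest", "kendall")) {
  significance <- match.arg(significance)
  check_matrix(df, complete = TRUE)
  design <- parse_design(df)
  times <- design$time
  period_bounds <- default_period_bounds(times, period_bounds)
  grid <- echo_grid(times, period_bounds, period_step, n_phases)
  vals <- values_matrix(df)
  rss_g <- if (nrow(vals)) grid_rss(grid, vals) else NULL
  rows <- purrr::map(seq_len(nrow(vals)), function(i) {
    fit <- fit_echo_series(vals[i, ], times, grid, period_bounds,
                           rss_g = rss_g[, i], n_starts = n_starts,
                           ac_max = ac_max)
    fit_row(fit, vals[i, ], times, df$feature_id[i], significance)
  })
  results <- dplyr::bind_rows(rows)
  if (nrow(results)) results$bh_q <- bh_adjust(results$p_value)
  structure(
    list(results = results, data = df, design = design,
         settings = list(period_bounds = period_bounds, n_starts = n_starts,
                         period_step = period_step, n_phases = n_phases,
                         ac_max = ac_max, significance = significance)),
    class = "echo_fit")
}

#' Restrict fit results to the circadian window
#'
#' Post-hoc ("postrun") restriction of free-run fits: keeps the oscillatory
#' results whose period lies inside `period_window` (bounds inclusive),
#' whose BH-adjusted p-value is strictly below `q_cutoff`, and whose AC
#' category is one of the circadian waveforms (damped, harmonic, forced).
#' The conventional windows are 20-28 h for transcripts and 18-30 h for
#' proteins, at q < 0.05.
#'
#' @param results A tidy results tibble (from [tidy()] on a fit object) or
#'   an `echo_fit`; must carry `period_h`, `bh_q` and `ac_category`.
#' @param period_window Inclusive period window `c(lo, hi)` in hours.
#' @param q_cutoff Strict BH-q cutoff.
#' @return The subset of `results` (as a tibble) meeting all conditions.
#' @export
postrun_restrict <- function(results, period_window = c(20, 28),
                             q_cutoff = 0.05) {
  if (inherits(results, "echo_fit")) results <- results$results
  if (length(period_window) != 2 || period_window[1] > period_window[2]) {
    abort("`period_window` lo must not exceed hi",
          class = "circatrend_invalid_window")
  }
  need <- c("period_h", "bh_q", "ac_category")
  if (!all(need %in% names(results))) {
    abort("`results` must carry period_h, bh_q and ac_category",
          class = "circatrend_invalid_input")
  }
  dplyr::filter(
    results,
    .data$period_h >= period_window[1],
    .data$period_h <= period_window[2],
    .data$bh_q < q_cutoff,
    .data$ac_category %in% ac_categories(circadian_only = TRUE),
    if ("model" %in% names(results)) {
      .data$model %in% c("echo", "echo_linear", "echo_joint",
                         "echo_linear_joint")
    } else TRUE
  )
}
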