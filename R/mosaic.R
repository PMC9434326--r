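## Trend-model library (linear, exponential, oscillator, oscillator+linear)
## and joint modeling of two correlated channels sharing period and phase.

fit_linear_series <- function(y, times) {
  X <- cbind(1, times)
  cf <- unname(qr.coef(qr(X), y))
  res <- y - X %*% cf
  list(model = "linear", slope = cf[2], baseline = cf[1],
       rss = sum(res^2), n_obs = length(y), k = 2, converged = TRUE)
}

## exponential a*exp(k*t)+c: deterministic rate grid with linear completion
## of (a, c), top starts refined by Levenberg-Marquardt; |rate| bounded by
## 1/h to prevent overflow
fit_exponential_series <- function(y, times, rate_max = 1) {
  rates <- c(-0.5, -0.2, -0.1, -0.05, -0.02, 0.02, 0.05, 0.1, 0.2, 0.5)
  comp <- lapply(rates, function(r) {
    X <- cbind(exp(r * times), 1)
    cf <- tryCatch(unname(qr.coef(qr(X), y)), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    list(rate = r, scale = cf[1], offset = cf[2],
         rss = sum((y - X %*% cf)^2))
  })
  comp <- comp[!vapply(comp, is.null, TRUE)]
  comp <- comp[order(vapply(comp, `[[`, 0, "rss"))]
  best <- NULL
  for (s in head(comp, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(k * tt) + c0,
        data = data.frame(y = y, tt = times),
        start = list(a = s$scale, k = s$rate, c0 = s$offset),
        lower = c(a = -Inf, k = -rate_max, c0 = -Inf),
        upper = c(a = Inf, k = rate_max, c0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(scale = cf[["a"]], rate = cf[["k"]], offset = cf[["c0"]],
                   rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(model = "exponential", scale = NA_real_, rate = NA_real_,
                offset = NA_real_, rss = Inf, n_obs = length(y), k = 3,
                converged = FALSE))
  }
  c(list(model = "exponential"), best,
    list(n_obs = length(y), k = 3, converged = TRUE))
}

fit_echo_linear_series <- function(y, times, grid, period_bounds,
                                   echo_fit = NULL, n_starts = 3,
                                   ac_max = 2) {
  ## starts: oscillator fit of the OLS-detrended series (+ its slope), and
  ## the plain oscillator fit with zero slope
  lin <- fit_linear_series(y, times)
  y_dt <- y - (lin$baseline + lin$slope * times)
  e_dt <- fit_echo_series(y_dt, times, grid, period_bounds,
                          n_starts = n_starts, ac_max = ac_max)
  starts <- list(
    list(A = e_dt$amplitude, g = e_dt$ac_coef, tau = e_dt$period,
         phi = e_dt$phase, y0 = e_dt$baseline + lin$baseline, m = lin$slope))
  if (!is.null(echo_fit) && echo_fit$amplitude > 0) {
    starts <- c(starts, list(
      list(A = echo_fit$amplitude, g = echo_fit$ac_coef,
           tau = echo_fit$period, phi = echo_fit$phase,
           y0 = echo_fit$baseline, m = 0)))
  }
  best <- NULL
  for (s in starts) {
    s$A <- max(s$A, 1e-8)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-g * tt / 2) * cos(2 * pi * tt / tau + phi) + y0 + m * tt,
        data = data.frame(y = y, tt = times),
        start = s,
        lower = c(A = 0, g = -ac_max, tau = period_bounds[1], phi = -2 * pi,
                  y0 = -Inf, m = -Inf),
        upper = c(A = Inf, g = ac_max, tau = period_bounds[2], phi = 4 * pi,
                  y0 = Inf, m = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 120)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(rss = rss, A = cf[["A"]], g = cf[["g"]], tau = cf[["tau"]],
                   phi = cf[["phi"]], y0 = cf[["y0"]], m = cf[["m"]])
    }
  }
  if (is.null(best)) {
    return(list(model = "echo_linear", amplitude = NA_real_,
                ac_coef = NA_real_, period = NA_real_, phase = NA_real_,
                baseline = NA_real_, slope = NA_real_, rss = Inf,
                n_obs = length(y), k = 6, converged = FALSE))
  }
  phi <- best$phi; A <- best$A
  if (A < 0) { A <- -A; phi <- phi + pi }
  list(model = "echo_linear", amplitude = A, ac_coef = best$g,
       period = best$tau, phase = phi %% (2 * pi), baseline = best$y0,
       slope = best$m, rss = best$rss, n_obs = length(y), k = 6,
       converged = TRUE)
}

## BIC with an RSS floor so numerically-zero residuals compare by parameter
## count alone (n ln(floor/n) is then shared and k ln n breaks the tie)
bic_of <- function(rss, n, k, scale = 1) {
  floor_rss <- n * (1e-6 * max(scale, 1e-8))^2
  n * log(max(rss, floor_rss) / n) + k * log(n)
}

#' Fit the trend-model library to one series
#'
#' Fits the four trend models — linear, exponential (\eqn{a e^{kt} + c}),
#' oscillator, and oscillator plus linear trend — independently and selects
#' the candidate minimizing \eqn{BIC = n \ln(RSS/n) + k \ln n}. Candidates
#' that fail to converge are excluded from selection but reported.
#'
#' @inheritParams fit_echo
#' @return A list with `best` (the winning model's one-row results tibble)
#'   and `candidates` (tibble of all four fits with `rss`, `bic`, `k`,
#'   `converged`).
#' @examples
#' t <- rep(seq(0, 48, 2), each = 3)
#' fit_trend_library(0.3 * t + 1, t)$best$model
#' @export
fit_trend_library <- function(values, times, period_bounds = NULL,
                              n_starts = 3, period_step = 2, n_phases = 8,
                              ac_max = 2) {
  if (length(values) != length(times) || anyNA(values)) {
    abort("`values` must be complete and match `times`",
          class = "circatrend_invalid_input")
  }
  period_bounds <- default_period_bounds(times, period_bounds)
  grid <- echo_grid(times, period_bounds, period_step, n_phases)
  trend_library_series(values, times, grid, period_bounds,
                       n_starts = n_starts, ac_max = ac_max,
                       feature_id = "series")
}

trend_library_series <- function(y, times, grid, period_bounds, rss_g = NULL,
                                 n_starts = 3, ac_max = 2,
                                 feature_id = "series") {
  n <- length(y)
  scale <- sd(y)
  lin <- fit_linear_series(y, times)
  expf <- fit_exponential_series(y, times)
  echo <- fit_echo_series(y, times, grid, period_bounds, rss_g = rss_g,
                          n_starts = n_starts, ac_max = ac_max)
  echo$k <- 5
  echol <- fit_echo_linear_series(y, times, grid, period_bounds,
                                  echo_fit = echo, n_starts = n_starts,
                                  ac_max = ac_max)
  cands <- list(linear = lin, exponential = expf, echo = echo,
                echo_linear = echol)
  cand_tbl <- purrr::map_dfr(cands, function(f) {
    tibble::tibble(
      feature_id = feature_id, model = f$model, k = f$k, n_obs = n,
      rss = f$rss, bic = if (f$converged) bic_of(f$rss, n, f$k, scale)
                         else NA_real_,
      converged = f$converged,
      period_h = f$period %||% NA_real_,
      phase_rad = f$phase %||% NA_real_,
      amplitude = f$amplitude %||% NA_real_,
      ac_coefficient = f$ac_coef %||% NA_real_,
      baseline = f$baseline %||% f$offset %||% NA_real_,
      slope = f$slope %||% NA_real_,
      scale = f$scale %||% NA_real_,
      rate = f$rate %||% NA_real_)
  })
  ok <- cand_tbl$converged
  if (!any(ok)) {
    sel <- cands$linear # linear always converges in practice
  } else {
    sel_name <- cand_tbl$model[ok][which.min(cand_tbl$bic[ok])]
    sel <- cands[[sel_name]]
  }
  rss0 <- sum((y - mean(y))^2)
  p <- oscillation_f_test(rss0, sel$rss, n, sel$k)
  best <- tibble::tibble(
    feature_id = feature_id,
    model = sel$model,
    period_h = sel$period %||% NA_real_,
    phase_rad = sel$phase %||% NA_real_,
    peak_time_h = if (!is.null(sel$period) && isTRUE(sel$amplitude > 0)) {
      ((-sel$phase) %% (2 * pi)) * sel$period / (2 * pi)
    } else NA_real_,
    amplitude = sel$amplitude %||% NA_real_,
    ac_coefficient = sel$ac_coef %||% NA_real_,
    ac_category = if (is.null(sel$ac_coef)) NA_character_
                  else as.character(classify_ac(sel$ac_coef)),
    baseline = sel$baseline %||% sel$offset %||% NA_real_,
    slope = sel$slope %||% NA_real_,
    rate = sel$rate %||% NA_real_,
    scale = sel$scale %||% NA_real_,
    rss = sel$rss,
    rmse = sqrt(sel$rss / n),
    n_obs = n,
    k = sel$k,
    p_value = p,
    converged = sel$converged)
  list(best = best, candidates = cand_tbl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the trend-model library to every feature
#'
#' Runs [fit_trend_library()] per feature with a shared vectorized period
#' grid and BH-adjusts the selected models' p-values across features.
#'
#' @inheritParams fit_rhythms
#' @return An object of class `trend_fit` with elements `results` (best
#'   model per feature, BH-adjusted) and `candidates` (all fits).
#' @export
fit_trends <- function(df, period_bounds = NULL, n_starts = 3,
                       period_step = 2, n_phases = 8, ac_max = 2) {
  check_matrix(df, complete = TRUE)
  design <- parse_design(df)
  times <- design$time
  period_bounds <- default_period_bounds(times, period_bounds)
  grid <- echo_grid(times, period_bounds, period_step, n_phases)
  vals <- values_matrix(df)
  rss_g <- if (nrow(vals)) grid_rss(grid, vals) else NULL
  fits <- purrr::map(seq_len(nrow(vals)), function(i) {
    trend_library_series(vals[i, ], times, grid, period_bounds,
                         rss_g = rss_g[, i], n_starts = n_starts,
                         ac_max = ac_max, feature_id = df$feature_id[i])
  })
  results <- dplyr::bind_rows(purrr::map(fits, "best"))
  if (nrow(results)) results$bh_q <- bh_adjust(results$p_value)
  structure(
    list(results = results,
         candidates = dplyr::bind_rows(purrr::map(fits, "candidates")),
         data = df, design = design,
         settings = list(period_bounds = period_bounds)),
    class = "trend_fit")
}
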