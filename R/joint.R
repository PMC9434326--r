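## Joint modeling of two correlated channels (e.g. transcript + protein):
## one weighted least-squares problem sharing period and phase across
## channels, with free per-channel amplitude, AC coefficient and baseline
## (plus per-channel slope in the linear variant). Channel weights are the
## inverse residual variances of the independent fits, with one reweighting
## iteration from the joint residuals.

joint_model_values <- function(p, t1, t2, linear) {
  osc <- function(A, g, b, t) {
    A * exp(-g * t / 2) * cos(2 * pi * t / p[["tau"]] + p[["phi"]]) + b
  }
  y1 <- osc(p[["A1"]], p[["g1"]], p[["b1"]], t1)
  y2 <- osc(p[["A2"]], p[["g2"]], p[["b2"]], t2)
  if (linear) {
    y1 <- y1 + p[["m1"]] * t1
    y2 <- y2 + p[["m2"]] * t2
  }
  c(y1, y2)
}

joint_nls <- function(y1, y2, t1, t2, start, w1, w2, period_bounds, ac_max,
                      linear) {
  yy <- c(y1, y2)
  swt <- sqrt(rep(c(w1, w2), c(length(y1), length(y2))))
  lower <- c(tau = period_bounds[1], phi = -2 * pi, A1 = 0, g1 = -ac_max,
             b1 = -Inf, A2 = 0, g2 = -ac_max, b2 = -Inf)
  upper <- c(tau = period_bounds[2], phi = 4 * pi, A1 = Inf, g1 = ac_max,
             b1 = Inf, A2 = Inf, g2 = ac_max, b2 = Inf)
  if (linear) {
    lower <- c(lower, m1 = -Inf, m2 = -Inf)
    upper <- c(upper, m1 = Inf, m2 = Inf)
  }
  par0 <- unlist(start)[names(lower)]
  par0 <- pmin(pmax(par0, lower), upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      fn = function(p) swt * (yy - joint_model_values(p, t1, t2, linear)),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  cf <- as.list(fit$par)
  cf$wrss <- fit$deviance
  cf
}

joint_start_from <- function(fit1, fit2, linear) {
  s <- list(tau = NA, phi = NA,
            A1 = max(fit1$amplitude, 1e-8), g1 = fit1$ac_coefficient,
            b1 = fit1$baseline,
            A2 = max(fit2$amplitude, 1e-8), g2 = fit2$ac_coefficient,
            b2 = fit2$baseline)
  if (linear) {
    s$m1 <- if (is.na(fit1$slope)) 0 else fit1$slope
    s$m2 <- if (is.na(fit2$slope)) 0 else fit2$slope
  }
  s
}

fit_joint_feature <- function(y1, y2, t1, t2, ind1, ind2, period_bounds,
                              ac_max = 2) {
  v1 <- sum((y1 - mean(y1))^2); v2 <- sum((y2 - mean(y2))^2)
  if (v1 < length(y1) * 1e-20 || v2 < length(y2) * 1e-20) {
    warn(paste0("constant channel for feature ", ind1$feature_id[1],
                ": joint fit falls back to independent fits"))
    return(NULL)
  }
  ## independent oscillator-family candidates supply starts and weights
  e1 <- ind1[ind1$model %in% c("echo", "echo_linear"), ][1, ]
  e2 <- ind2[ind2$model %in% c("echo", "echo_linear"), ][1, ]
  w1 <- 1 / max(e1$rss / e1$n_obs, 1e-12)
  w2 <- 1 / max(e2$rss / e2$n_obs, 1e-12)
  linear <- any(c(e1$model, e2$model) == "echo_linear")
  fits <- list()
  for (lin in unique(c(FALSE, linear))) {
    for (lead in if (w1 >= w2) list(e1, e2) else list(e2, e1)) {
      if (!isTRUE(lead$amplitude > 0)) next
      st <- joint_start_from(e1, e2, lin)
      st$tau <- min(max(lead$period_h, period_bounds[1]), period_bounds[2])
      st$phi <- lead$phase_rad
      f <- joint_nls(y1, y2, t1, t2, st, w1, w2, period_bounds, ac_max, lin)
      if (!is.null(f)) {
        ## one reweighting iteration from joint residuals
        r1 <- y1 - joint_channel_curve(f, t1, 1, lin)
        r2 <- y2 - joint_channel_curve(f, t2, 2, lin)
        w1b <- 1 / max(mean(r1^2), 1e-12)
        w2b <- 1 / max(mean(r2^2), 1e-12)
        st2 <- f; st2$wrss <- NULL
        f2 <- joint_nls(y1, y2, t1, t2, st2, w1b, w2b, period_bounds,
                        ac_max, lin)
        if (!is.null(f2)) { f <- f2; w1 <- w1b; w2 <- w2b }
        f$linear <- lin; f$w1 <- w1; f$w2 <- w2
        f$k <- if (lin) 10 else 8
        n_tot <- length(y1) + length(y2)
        f$bic <- n_tot * log(max(f$wrss, n_tot * 1e-20) / n_tot) +
          f$k * log(n_tot)
        fits[[length(fits) + 1]] <- f
        break # one converged start per variant suffices
      }
    }
  }
  if (!length(fits)) return(NULL)
  fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
}

joint_channel_curve <- function(cf, t, channel, linear) {
  A <- cf[[paste0("A", channel)]]; g <- cf[[paste0("g", channel)]]
  b <- cf[[paste0("b", channel)]]
  y <- A * exp(-g * t / 2) * cos(2 * pi * t / cf$tau + cf$phi) + b
  if (linear) y <- y + cf[[paste0("m", channel)]] * t
  y
}

joint_channel_row <- function(cf, y, t, channel, feature_id, channel_name) {
  linear <- isTRUE(cf$linear)
  A <- cf[[paste0("A", channel)]]
  phi <- cf$phi
  if (A < 0) { A <- -A; phi <- phi + pi }
  phi <- phi %% (2 * pi)
  curve <- joint_channel_curve(cf, t, channel, linear)
  rss <- sum((y - curve)^2)
  rss0 <- sum((y - mean(y))^2)
  n <- length(y)
  ## shared parameters (tau, phi) are charged to the channel carrying the
  ## larger weight: the noisier channel tests its oscillation conditional
  ## on the timing established by the cleaner one. Equal weights charge
  ## both channels in full.
  wts <- c(cf$w1, cf$w2)
  shared_k <- if (wts[channel] >= wts[-channel]) 2 else 0
  k <- (if (linear) 4 else 3) + shared_k
  w_frac <- wts[channel] / sum(wts)
  g <- cf[[paste0("g", channel)]]
  tibble::tibble(
    feature_id = feature_id,
    channel = channel_name,
    model = if (linear) "echo_linear_joint" else "echo_joint",
    period_h = cf$tau,
    phase_rad = phi,
    peak_time_h = if (A > 0) ((-phi) %% (2 * pi)) * cf$tau / (2 * pi)
                  else NA_real_,
    amplitude = A,
    ac_coefficient = g,
    ac_category = as.character(classify_ac(g)),
    baseline = cf[[paste0("b", channel)]],
    slope = if (linear) cf[[paste0("m", channel)]] else NA_real_,
    rss = rss,
    rmse = sqrt(rss / n),
    n_obs = n,
    k = k,
    weight = w_frac,
    p_value = oscillation_f_test(rss0, rss, n, k),
    converged = TRUE)
}

#' Jointly model two paired omics channels
#'
#' Fits the trend library independently per channel, then fits each shared
#' feature as a single weighted least-squares problem in which the two
#' channels share the oscillation period and phase but keep free per-channel
#' amplitude, AC coefficient and baseline (and slope, in the linear
#' variant). Channel weights are inverse residual variances from the
#' independent fits, updated by one reweighting iteration. Features lacking
#' detectable expression in either channel are dropped (paired-presence
#' filter). Per-channel significance comes from nested F-tests; trend
#' labels follow [assign_trend_label()].
#'
#' @param df_a,df_b Complete wide expression tibbles for the cleaner (e.g.
#'   RNA) and noisier (e.g. protein) channel.
#' @param channels Length-2 channel names used in the output.
#' @param period_windows Named list of inclusive circadian period windows
#'   per channel (h) used for labeling; defaults to 20-28 for the first
#'   channel and 18-30 for the second.
#' @param q_cutoff Strict BH-q significance cutoff.
#' @inheritParams fit_rhythms
#' @return An object of class `mosaic_fit`: `results` (one labeled row per
#'   feature per channel, showing the parameters of the model behind the
#'   label), `independent` (per-channel `trend_fit` results), `joint`
#'   (joint-model rows) and `candidates`.
#' @export
fit_joint_rhythms <- function(df_a, df_b, channels = c("rna", "protein"),
                              period_bounds = NULL,
                              period_windows = NULL, q_cutoff = 0.05,
                              n_starts = 3, period_step = 2, n_phases = 8,
                              ac_max = 2) {
  if (is.null(period_windows)) {
    period_windows <- setNames(list(c(20, 28), c(18, 30)), channels)
  }
  paired <- paired_presence_filter(df_a, df_b)
  check_matrix(paired$a, complete = TRUE)
  check_matrix(paired$b, complete = TRUE)
  ind_a <- fit_trends(paired$a, period_bounds, n_starts, period_step,
                      n_phases, ac_max)
  ind_b <- fit_trends(paired$b, period_bounds, n_starts, period_step,
                      n_phases, ac_max)
  des_a <- ind_a$design; des_b <- ind_b$design
  pb <- default_period_bounds(c(des_a$time, des_b$time), period_bounds)
  va <- values_matrix(paired$a); vb <- values_matrix(paired$b)
  joint_rows <- purrr::map_dfr(seq_len(nrow(va)), function(i) {
    fid <- paired$a$feature_id[i]
    ca <- ind_a$candidates[ind_a$candidates$feature_id == fid, ]
    cb <- ind_b$candidates[ind_b$candidates$feature_id == fid, ]
    cf <- fit_joint_feature(va[i, ], vb[i, ], des_a$time, des_b$time,
                            ca, cb, pb, ac_max)
    if (is.null(cf)) return(tibble::tibble())
    dplyr::bind_rows(
      joint_channel_row(cf, va[i, ], des_a$time, 1, fid, channels[1]),
      joint_channel_row(cf, vb[i, ], des_b$time, 2, fid, channels[2]))
  })
  if (nrow(joint_rows)) {
    joint_rows <- joint_rows |>
      dplyr::group_by(.data$channel) |>
      dplyr::mutate(bh_q = bh_adjust(.data$p_value)) |>
      dplyr::ungroup()
  }
  ind <- dplyr::bind_rows(
    dplyr::mutate(ind_a$results, channel = channels[1], .after = 1),
    dplyr::mutate(ind_b$results, channel = channels[2], .after = 1))
  results <- label_results(ind, joint_rows, period_windows, q_cutoff)
  structure(
    list(results = results, independent = ind, joint = joint_rows,
         candidates = list(dplyr::bind_rows(ind_a$candidates),
                           dplyr::bind_rows(ind_b$candidates)) |>
           setNames(channels),
         settings = list(period_bounds = pb, period_windows = period_windows,
                         q_cutoff = q_cutoff, channels = channels)),
    class = "mosaic_fit")
}

circadian_call <- function(row, window, q_cutoff) {
  isTRUE(row$model %in% c("echo", "echo_linear", "echo_joint",
                          "echo_linear_joint")) &&
    isTRUE(row$bh_q < q_cutoff) &&
    isTRUE(row$period_h >= window[1] && row$period_h <= window[2]) &&
    isTRUE(row$ac_category %in% ac_categories(circadian_only = TRUE))
}

#' Assign the six-way trend label for one channel of one feature
#'
#' Labels follow the precedence: an oscillation significant in the
#' channel's independent fit is `"ECHO"` (or `"ECHO Linear"` when the
#' selected model carries a linear trend); an oscillation only significant
#' under joint modeling is `"ECHO Joint"` (or `"ECHO Linear Joint"`);
#' otherwise a significant nonoscillatory model gives `"Linear"` or
#' `"Exponential"`; anything else is unlabeled (`NA`). Oscillatory calls
#' additionally require the period inside the circadian window and a
#' circadian AC category.
#'
#' @param independent One-row tibble: the channel's independent best-model
#'   fit (with `model`, `period_h`, `ac_category`, `bh_q`).
#' @param joint One-row tibble or `NULL`: the channel's joint-model fit.
#' @param period_window Inclusive circadian period window (h).
#' @param q_cutoff Strict BH-q cutoff.
#' @return A single character label or `NA`.
#' @export
assign_trend_label <- function(independent, joint, period_window,
                               q_cutoff = 0.05) {
  if (circadian_call(independent, period_window, q_cutoff)) {
    return(if (independent$model == "echo_linear") "ECHO Linear" else "ECHO")
  }
  if (!is.null(joint) && nrow(joint) == 1 &&
      circadian_call(joint, period_window, q_cutoff)) {
    return(if (joint$model == "echo_linear_joint") "ECHO Linear Joint"
           else "ECHO Joint")
  }
  if (isTRUE(independent$model %in% c("linear", "exponential")) &&
      isTRUE(independent$bh_q < q_cutoff)) {
    return(if (independent$model == "linear") "Linear" else "Exponential")
  }
  NA_character_
}

label_results <- function(ind, joint_rows, period_windows, q_cutoff) {
  purrr::map_dfr(seq_len(nrow(ind)), function(i) {
    row <- ind[i, ]
    win <- period_windows[[row$channel]]
    j <- if (nrow(joint_rows)) {
      joint_rows[joint_rows$feature_id == row$feature_id &
                   joint_rows$channel == row$channel, ]
    } else NULL
    if (!is.null(j) && nrow(j) != 1) j <- NULL
    label <- assign_trend_label(row, j, win, q_cutoff)
    src <- if (isTRUE(label %in% c("ECHO Joint", "ECHO Linear Joint"))) {
      j
    } else row
    src$trend_label <- label
    src$channel <- row$channel
    src
  })
}

#' Tabulate trend labels
#'
#' Counts and percentages per trend category (per channel when a `channel`
#' column is present). Unlabeled rows are dropped from the tabulation;
#' percentages are relative to the labeled total.
#'
#' @param labels A character vector of trend labels, or a results tibble
#'   with a `trend_label` (and optionally `channel`) column.
#' @return A tibble with columns (`channel`,) `trend_label`, `n`, `pct`.
#' @examples
#' trend_distribution(c("ECHO", "ECHO", "Linear"))
#' @export
trend_distribution <- function(labels) {
  lvls <- c("Linear", "Exponential", "ECHO", "ECHO Joint", "ECHO Linear",
            "ECHO Linear Joint")
  if (is.data.frame(labels)) {
    df <- labels
    if (!"trend_label" %in% names(df)) {
      abort("results must carry a trend_label column",
            class = "circatrend_invalid_input")
    }
    if (!"channel" %in% names(df)) df$channel <- "all"
  } else {
    df <- tibble::tibble(trend_label = labels, channel = "all")
  }
  df <- df[!is.na(df$trend_label), ]
  out <- df |>
    dplyr::count(.data$channel,
                 trend_label = factor(.data$trend_label, levels = lvls),
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n)
                  else 0) |>
    dplyr::ungroup() |>
    dplyr::mutate(trend_label = as.character(.data$trend_label))
  if (identical(unique(out$channel), "all")) {
    out$channel <- NULL
  }
  out
}
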