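#' Filter features by detection presence
#'
#' Keeps the features whose fraction of non-missing samples is at least
#' `min_fraction` (boundary inclusive), preserving row order. The
#' conventional cutoff removes transcripts or proteins detected in fewer
#' than 70% of samples.
#'
#' @param df Wide expression tibble (`feature_id` + sample columns).
#' @param min_fraction Minimum fraction of non-missing samples in (0, 1].
#' @return Filtered tibble.
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b"),
#'                     `0.1` = c(1, NA), `2.1` = c(2, NA), `4.1` = c(3, 1))
#' presence_filter(m, 0.5)
#' @export
presence_filter <- function(df, min_fraction = 0.7) {
  check_matrix(df)
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    abort("`min_fraction` must be in (0, 1]",
          class = "circatrend_invalid_parameter")
  }
  vals <- values_matrix(df)
  frac <- rowMeans(!is.na(vals))
  df[frac >= min_fraction, , drop = FALSE]
}

#' Impute missing values
#'
#' Fills missing entries per feature. The default interpolates linearly in
#' time within each replicate series, extrapolating constantly at the ends;
#' a replicate series with fewer than 2 observed points — or the `"mean"`
#' method — falls back to the feature mean over all observed samples.
#' Non-missing entries are never altered.
#'
#' @param df Wide expression tibble; every feature must have at least one
#'   observed value (run [presence_filter()] first).
#' @param method `"linear"` (default) or `"mean"`.
#' @return Tibble with no missing values.
#' @export
impute_missing <- function(df, method = c("linear", "mean")) {
  check_matrix(df)
  method <- match.arg(method)
  design <- parse_design(df)
  vals <- values_matrix(df)
  if (!nrow(vals) || !anyNA(vals)) return(df)
  if (any(rowSums(!is.na(vals)) == 0)) {
    abort("all-missing feature cannot be imputed; run presence_filter() first",
          class = "circatrend_invalid_parameter")
  }
  rep_groups <- split(seq_len(nrow(design)), design$replicate)
  for (i in seq_len(nrow(vals))) {
    y <- vals[i, ]
    if (!anyNA(y)) next
    fmean <- mean(y, na.rm = TRUE)
    if (method == "linear") {
      for (idx in rep_groups) {
        ord <- idx[order(design$time[idx])]
        yr <- y[ord]
        if (sum(!is.na(yr)) >= 2) {
          y[ord] <- zoo::na.approx(yr, x = design$time[ord], rule = 2)
        } else {
          y[ord][is.na(yr)] <- fmean
        }
      }
    } else {
      y[is.na(y)] <- fmean
    }
    vals[i, ] <- y
  }
  df[sample_cols(df)] <- vals
  df
}

#' Z-score each feature
#'
#' Centers and scales each feature row to mean 0 and unit sample standard
#' deviation (denominator \eqn{n - 1}). Constant rows map to all zeros.
#'
#' @param df Complete wide expression tibble.
#' @return Z-scored tibble.
#' @export
zscore_rows <- function(df) {
  check_matrix(df, complete = TRUE)
  vals <- values_matrix(df)
  if (nrow(vals)) {
    mu <- rowMeans(vals)
    sdv <- apply(vals, 1, sd)
    sdv[sdv == 0] <- Inf # constant rows -> zeros
    vals <- (vals - mu) / sdv
  }
  df[sample_cols(df)] <- vals
  df
}

#' Remove a linear trend from each feature
#'
#' Subtracts the per-feature ordinary least-squares line over time, leaving
#' residuals with zero slope and zero mean. Idempotent.
#'
#' @param df Complete wide expression tibble.
#' @return De-trended tibble.
#' @export
detrend_linear <- function(df) {
  check_matrix(df, complete = TRUE)
  design <- parse_design(df)
  vals <- values_matrix(df)
  if (nrow(vals)) {
    X <- cbind(1, design$time)
    coefs <- qr.coef(qr(X), t(vals)) # 2 x n_features
    vals <- vals - t(X %*% coefs)
  }
  df[sample_cols(df)] <- vals
  df
}

#' Smooth each feature along time
#'
#' Applies a centered weighted moving average along the timepoints within
#' each replicate series. At the series ends the kernel is renormalized over
#' the available neighbours. With fewer than 3 timepoints the input is
#' returned unchanged.
#'
#' @param df Complete wide expression tibble.
#' @param weights Symmetric odd-length kernel; default `c(1, 2, 1)` (i.e.
#'   1-2-1/4 smoothing).
#' @return Smoothed tibble.
#' @export
smooth_rows <- function(df, weights = c(1, 2, 1)) {
  check_matrix(df, complete = TRUE)
  if (length(weights) %% 2 != 1 || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be a non-negative odd-length kernel",
          class = "circatrend_invalid_parameter")
  }
  design <- parse_design(df)
  if (length(unique(design$time)) < 3) return(df)
  vals <- values_matrix(df)
  half <- (length(weights) - 1) / 2
  rep_groups <- split(seq_len(nrow(design)), design$replicate)
  out <- vals
  for (idx in rep_groups) {
    ord <- idx[order(design$time[idx])]
    nt <- length(ord)
    ## smoothing matrix: rows renormalized at boundaries
    S <- matrix(0, nt, nt)
    for (j in seq_len(nt)) {
      nb <- (j - half):(j + half)
      ok <- nb >= 1 & nb <= nt
      w <- weights[ok]
      S[j, nb[ok]] <- w / sum(w)
    }
    out[, ord] <- vals[, ord, drop = FALSE] %*% t(S)
  }
  df[sample_cols(df)] <- out
  df
}

#' Restrict two channels to their shared features
#'
#' Joint modeling requires detectable expression at both omic levels; this
#' drops every feature absent from either channel and returns both matrices
#' restricted to the intersection, in the first matrix's feature order.
#'
#' @param df_a,df_b Wide expression tibbles for the two channels.
#' @return Named list with elements `a` and `b`.
#' @export
paired_presence_filter <- function(df_a, df_b) {
  check_matrix(df_a); check_matrix(df_b)
  shared <- intersect(df_a$feature_id, df_b$feature_id)
  if (!length(shared)) {
    warn("no features shared between the two channels")
  }
  list(a = df_a[match(shared, df_a$feature_id), , drop = FALSE],
       b = df_b[match(shared, df_b$feature_id), , drop = FALSE])
}

#' Full data-conditioning chain
#'
#' Convenience wrapper running, in order, [presence_filter()],
#' [impute_missing()], [zscore_rows()], and — when enabled —
#' [detrend_linear()] and [smooth_rows()]. The default chain stops at
#' z-scoring: linear detrending removes part of the envelope trend of
#' strongly amplitude-changing oscillators and is better handled by the
#' explicit linear-trend models of the library, and moving-average
#' smoothing correlates residuals, which invalidates the calibration of
#' the nested F-test under the null. Both steps remain available for data
#' with genuine baseline drift or for visualization.
#'
#' @inheritParams presence_filter
#' @inheritParams impute_missing
#' @inheritParams smooth_rows
#' @param detrend If `TRUE`, subtract the per-feature OLS line after
#'   z-scoring.
#' @param smooth If `TRUE`, apply the moving-average smoother last.
#' @return Conditioned tibble with no missing values.
#' @export
preprocess <- function(df, min_fraction = 0.7, method = "linear",
                       detrend = FALSE, smooth = FALSE,
                       weights = c(1, 2, 1)) {
  out <- df |>
    presence_filter(min_fraction) |>
    impute_missing(method) |>
    zscore_rows()
  if (detrend) out <- detrend_linear(out)
  if (smooth) out <- smooth_rows(out, weights)
  out
}
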