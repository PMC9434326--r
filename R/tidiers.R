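#' Tidy a rhythm fit
#'
#' @param x An `echo_fit`, `trend_fit` or `mosaic_fit` object.
#' @param ... Unused.
#' @return The per-feature (per channel, for joint fits) results tibble.
#' @export
tidy.echo_fit <- function(x, ...) x$results

#' @rdname tidy.echo_fit
#' @export
tidy.trend_fit <- function(x, ...) x$results

#' @rdname tidy.echo_fit
#' @export
tidy.mosaic_fit <- function(x, ...) x$results

#' Summarize a rhythm fit in one row
#'
#' @param x An `echo_fit`, `trend_fit` or `mosaic_fit`.
#' @param q_cutoff Strict BH-q cutoff used for the significance counts.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.echo_fit <- function(x, q_cutoff = 0.05, ...) {
  r <- x$results
  tibble::tibble(
    n_features = nrow(r),
    n_converged = sum(r$converged),
    n_significant = sum(r$bh_q < q_cutoff),
    median_period_h = stats::median(r$period_h),
    period_lo = x$settings$period_bounds[1],
    period_hi = x$settings$period_bounds[2])
}

#' @rdname glance.echo_fit
#' @export
glance.trend_fit <- function(x, q_cutoff = 0.05, ...) {
  r <- x$results
  tibble::tibble(
    n_features = nrow(r),
    n_converged = sum(r$converged),
    n_significant = sum(r$bh_q < q_cutoff)) |>
    dplyr::bind_cols(
      tidyr::pivot_wider(dplyr::count(r, .data$model),
                         names_from = "model", values_from = "n",
                         names_prefix = "n_model_"))
}

#' @rdname glance.echo_fit
#' @export
glance.mosaic_fit <- function(x, q_cutoff = 0.05, ...) {
  r <- x$results
  tibble::tibble(
    n_features = length(unique(r$feature_id)),
    n_labeled = sum(!is.na(r$trend_label)),
    n_joint_only = sum(r$trend_label %in%
                         c("ECHO Joint", "ECHO Linear Joint")))
}

#' @export
print.echo_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<echo_fit> %d features, %d converged, %d with BH q < 0.05 (free-run %g-%g h)\n",
    g$n_features, g$n_converged, g$n_significant, g$period_lo, g$period_hi))
  print(x$results, n = 5)
  invisible(x)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %d features; model counts:\n", nrow(x$results)))
  print(table(x$results$model))
  invisible(x)
}

#' @export
print.mosaic_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mosaic_fit> %d features x %d channels, %d labeled (%d joint-only)\n",
    g$n_features, length(x$settings$channels), g$n_labeled, g$n_joint_only))
  print(trend_distribution(x$results))
  invisible(x)
}

fitted_curve_data <- function(results, design, times_out = NULL) {
  if (is.null(times_out)) {
    times_out <- seq(min(design$time), max(design$time), length.out = 200)
  }
  purrr::map_dfr(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    y <- if (r$model %in% c("echo", "echo_joint", "echo_linear",
                            "echo_linear_joint")) {
      echo_curve(times_out, list(amplitude = r$amplitude,
                                 ac_coef = r$ac_coefficient,
                                 period = r$period_h, phase = r$phase_rad,
                                 baseline = r$baseline)) +
        (if (!is.na(r$slope)) r$slope * times_out else 0)
    } else if (r$model == "linear") {
      r$slope * times_out + r$baseline
    } else if (r$model == "exponential") {
      r$scale * exp(r$rate * times_out) + r$baseline
    } else {
      rep(NA_real_, length(times_out))
    }
    tibble::tibble(feature_id = r$feature_id, time = times_out, fitted = y)
  })
}

#' Plot fitted curves over the data
#'
#' Draws, for a subset of features, the observed replicate points over time
#' together with the fitted model curve, one facet per feature.
#'
#' @param object An `echo_fit`.
#' @param features Character vector of feature ids (default: up to 6 most
#'   significant).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.echo_fit <- function(object, features = NULL, ...) {
  r <- object$results
  if (is.null(features)) {
    features <- head(r$feature_id[order(r$p_value)], 6)
  }
  r <- r[r$feature_id %in% features, ]
  df <- object$data[object$data$feature_id %in% features, ]
  long <- tidyr::pivot_longer(df, -"feature_id", names_to = "column",
                              values_to = "value") |>
    dplyr::left_join(object$design, by = "column")
  curves <- fitted_curve_data(r, object$design)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$fitted), color = "#2166ac") +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = "time (h post synchronization)",
                  y = "expression (z-units)")
}

#' Plot the distribution of trend labels
#'
#' Stacked horizontal bar of trend-category percentages per channel, the
#' standard summary view of a joint-modeling run.
#'
#' @param x A `mosaic_fit`, a labeled results tibble, or the output of
#'   [trend_distribution()].
#' @return A ggplot object.
#' @export
plot_trend_distribution <- function(x) {
  if (inherits(x, "mosaic_fit")) x <- x$results
  dist <- if (all(c("n", "pct") %in% names(x))) x else trend_distribution(x)
  if (!"channel" %in% names(dist)) dist$channel <- "all"
  ggplot2::ggplot(dist,
                  ggplot2::aes(x = .data$pct, y = .data$channel,
                               fill = .data$trend_label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = "% of labeled features", y = NULL)
}

#' @rdname autoplot.echo_fit
#' @export
autoplot.mosaic_fit <- function(object, ...) plot_trend_distribution(object)
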