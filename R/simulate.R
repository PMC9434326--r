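#' Specification for a synthetic paired time-course dataset
#'
#' Describes the simulated study: a dense circadian sampling design
#' (default 0-48 h every 2 h, 3 replicates — 25 timepoints x 3) measured in
#' two channels with channel-specific Gaussian noise on the z-scored scale
#' (default RNA 0.2, protein 0.8 z-units — the protein channel is the
#' noisier one). Features are drawn per trend class; oscillator parameters
#' are sampled with circadian periods (20-28 h), amplitudes 0.5-2 z-units,
#' uniform phase, zero baseline, and AC coefficients inside the class band
#' (harmonic within \eqn{\pm 0.15}/h, damped/forced in \eqn{\pm(0.15,
#' 0.3]}/h). Paired channels share period and phase and draw amplitude and
#' AC coefficient independently, mirroring the joint-model structure.
#'
#' @param n_features Named integer vector of feature counts per class;
#'   recognized classes: `flat`, `linear`, `exponential`, `harmonic`,
#'   `damped`, `forced`, `echo_linear`.
#' @param timepoints Sampling times (h).
#' @param replicates Replicates per timepoint.
#' @param noise_sd Named per-channel noise SD (z-units).
#' @param period_range,amplitude_range Uniform sampling ranges.
#' @param ac_bands Named list of AC-coefficient bands per oscillatory class.
#' @param slope_range,rate_range Magnitude ranges for linear slope (z/h) and
#'   exponential rate (1/h); signs are drawn at random.
#' @param missing_rate Fraction of cells set missing, uniformly at random.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_features = c(harmonic = 20, damped = 20, forced = 20,
                                    flat = 20, linear = 10,
                                    exponential = 10, echo_linear = 10),
                     timepoints = seq(0, 48, by = 2), replicates = 3,
                     noise_sd = c(rna = 0.2, protein = 0.8),
                     period_range = c(20, 28), amplitude_range = c(0.5, 2),
                     ac_bands = list(harmonic = c(-0.15, 0.15),
                                     damped = c(0.15, 0.3),
                                     forced = c(-0.3, -0.15)),
                     slope_range = c(0.01, 0.04),
                     rate_range = c(0.02, 0.06),
                     missing_rate = 0) {
  known <- c("flat", "linear", "exponential", "harmonic", "damped", "forced",
             "echo_linear")
  if (is.null(names(n_features)) || !all(names(n_features) %in% known)) {
    abort(paste("`n_features` must be named with classes among:",
                paste(known, collapse = ", ")),
          class = "circatrend_invalid_parameter")
  }
  if (any(noise_sd < 0) || is.null(names(noise_sd))) {
    abort("`noise_sd` must be named and non-negative",
          class = "circatrend_invalid_parameter")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1)",
          class = "circatrend_invalid_parameter")
  }
  if (missing_rate >= 0.3) {
    warn("missing rate >= 30%: features may fall below the presence filter")
  }
  structure(list(n_features = n_features, timepoints = timepoints,
                 replicates = replicates, noise_sd = noise_sd,
                 period_range = period_range,
                 amplitude_range = amplitude_range, ac_bands = ac_bands,
                 slope_range = slope_range, rate_range = rate_range,
                 missing_rate = missing_rate),
            class = "sim_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) abort("`seed` is mandatory",
                           class = "circatrend_invalid_parameter")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

runif_band <- function(band) runif(1, band[1], band[2])

draw_channel_params <- function(class, spec, shared) {
  p <- list(class = class, period = shared$period, phase = shared$phase,
            baseline = 0, amplitude = NA_real_, ac_coef = NA_real_,
            slope = NA_real_, rate = NA_real_, scale = NA_real_)
  if (class %in% c("harmonic", "damped", "forced", "echo_linear")) {
    band <- if (class == "echo_linear") spec$ac_bands$harmonic
            else spec$ac_bands[[class]]
    p$amplitude <- runif_band(spec$amplitude_range)
    p$ac_coef <- runif_band(band)
  }
  if (class %in% c("linear", "echo_linear")) {
    p$slope <- sample(c(-1, 1), 1) * runif_band(spec$slope_range)
  }
  if (class == "exponential") {
    p$rate <- sample(c(-1, 1), 1) * runif_band(spec$rate_range)
    p$scale <- sample(c(-1, 1), 1) * runif_band(spec$amplitude_range)
  }
  p
}

channel_curve <- function(p, t) {
  y <- rep(p$baseline, length(t))
  if (!is.na(p$amplitude)) {
    y <- y + p$amplitude * exp(-p$ac_coef * t / 2) *
      cos(2 * pi * t / p$period + p$phase)
  }
  if (!is.na(p$slope)) y <- y + p$slope * t
  if (!is.na(p$rate)) y <- y + p$scale * exp(p$rate * t)
  y
}

#' Simulate a paired two-channel time-course dataset with ground truth
#'
#' Generates one wide expression matrix per channel plus a truth table.
#' Values are the class's model curve plus iid Gaussian noise per sample;
#' missingness (if requested) is applied uniformly at random afterwards.
#' Deterministic for a given spec and seed.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed (mandatory).
#' @return A list with one wide tibble per channel (named as in
#'   `spec$noise_sd`) and `truth`, a tibble with one row per feature per
#'   channel holding the class and generating parameters (`period` and
#'   `phase` shared across channels).
#' @examples
#' sim <- simulate_dataset(sim_spec(n_features = c(harmonic = 2)), seed = 1)
#' names(sim)
#' @export
simulate_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(seed, {
    t_all <- rep(spec$timepoints, each = spec$replicates)
    rep_all <- rep(seq_len(spec$replicates), length(spec$timepoints))
    cols <- paste0(t_all, ".", rep_all)
    channels <- names(spec$noise_sd)
    classes <- rep(names(spec$n_features), spec$n_features)
    ids <- sprintf("feat_%03d_%s", seq_along(classes), classes)
    truth <- list(); mats <- lapply(channels, function(ch) NULL)
    names(mats) <- channels
    rows <- lapply(channels, function(ch) {
      matrix(NA_real_, length(ids), length(cols),
             dimnames = list(ids, cols))
    })
    names(rows) <- channels
    for (i in seq_along(ids)) {
      shared <- list(period = runif_band(spec$period_range),
                     phase = runif(1, 0, 2 * pi))
      for (ch in channels) {
        p <- draw_channel_params(classes[i], spec, shared)
        y <- channel_curve(p, t_all) +
          rnorm(length(t_all), 0, spec$noise_sd[[ch]])
        if (spec$missing_rate > 0) {
          y[runif(length(y)) < spec$missing_rate] <- NA_real_
        }
        rows[[ch]][i, ] <- y
        truth[[length(truth) + 1]] <- tibble::tibble(
          feature_id = ids[i], channel = ch, class = classes[i],
          period = p$period, phase = p$phase, amplitude = p$amplitude,
          ac_coef = p$ac_coef, baseline = p$baseline, slope = p$slope,
          rate = p$rate, scale = p$scale)
      }
    }
    out <- lapply(channels, function(ch) {
      dplyr::bind_cols(tibble::tibble(feature_id = ids),
                       tibble::as_tibble(rows[[ch]]))
    })
    names(out) <- channels
    out$truth <- dplyr::bind_rows(truth)
    out
  })
}

circular_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Compare fit results against simulation ground truth
#'
#' Computes parameter-recovery and detection metrics for one channel:
#' period mean absolute error and the fraction recovered within \eqn{\pm}1 h,
#' circular phase error, AC-category confusion and accuracy over the
#' oscillatory classes, and detection recall / false discovery rate where a
#' detection is a BH-q below `q_cutoff` inside the circadian window with a
#' circadian AC category.
#'
#' @param results Tidy per-feature results (from [tidy()] on an `echo_fit`,
#'   or any tibble with `feature_id`, `period_h`, `phase_rad`,
#'   `ac_coefficient`, `ac_category`, `bh_q`).
#' @param truth Truth tibble from [simulate_dataset()], already filtered to
#'   the matching channel.
#' @param q_cutoff,period_window Detection thresholds.
#' @return A list with `metrics` (one-row tibble) and `confusion` (tibble
#'   of true class x estimated category counts).
#' @export
recovery_report <- function(results, truth, q_cutoff = 0.05,
                            period_window = c(20, 28)) {
  if (inherits(results, "echo_fit")) results <- results$results
  if (!nrow(results) || !nrow(truth)) {
    return(list(metrics = tibble::tibble(), confusion = tibble::tibble()))
  }
  if ("channel" %in% names(truth) && length(unique(truth$channel)) > 1) {
    abort("filter `truth` to a single channel first",
          class = "circatrend_invalid_input")
  }
  osc_classes <- c("harmonic", "damped", "forced", "echo_linear")
  joined <- dplyr::inner_join(results, truth, by = "feature_id")
  osc <- joined[joined$class %in% osc_classes, ]
  detected <- joined$bh_q < q_cutoff &
    joined$period_h >= period_window[1] &
    joined$period_h <= period_window[2] &
    joined$ac_category %in% ac_categories(circadian_only = TRUE)
  is_osc <- joined$class %in% osc_classes
  pure <- joined[joined$class %in% c("harmonic", "damped", "forced"), ]
  metrics <- tibble::tibble(
    n_features = nrow(joined),
    n_oscillatory = nrow(osc),
    period_mae = mean(abs(osc$period_h - osc$period)),
    period_within_1h = mean(abs(osc$period_h - osc$period) <= 1),
    phase_mae_rad = mean(circular_diff(osc$phase_rad, osc$phase)),
    category_accuracy = mean(pure$ac_category == pure$class),
    recall = if (any(is_osc)) mean(detected[is_osc]) else NA_real_,
    fdr = if (any(detected)) mean(!is_osc[detected]) else 0)
  confusion <- pure |>
    dplyr::count(true_class = .data$class,
                 estimated = .data$ac_category) |>
    tidyr::pivot_wider(names_from = "estimated", values_from = "n",
                       values_fill = 0L)
  list(metrics = metrics, confusion = confusion)
}
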