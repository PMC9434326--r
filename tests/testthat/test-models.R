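test_that("oscillator curve matches closed-form values", {
  expect_equal(echo_curve(0, echo_params(1, 0, 24, 0)), 1)
  # zero amplitude collapses to the baseline everywhere
  expect_equal(echo_curve(c(0, 7, 31), echo_params(0, 0.3, 24, 1, 2.5)),
               rep(2.5, 3))
  expect_equal(echo_curve(12, echo_params(1, 0.1, 24, 0)),
               -0.548811636094026, tolerance = 1e-12)
})

test_that("undamped oscillator is exactly periodic; gamma=0 is a pure cosine", {
  set.seed(11)
  t <- seq(0, 96, by = 0.5)
  for (i in 1:20) {
    p <- echo_params(runif(1, 0.1, 3), 0, runif(1, 16, 32),
                     runif(1, 0, 2 * pi), runif(1, -1, 1))
    y <- echo_curve(t, p)
    expect_equal(y, p$amplitude * cos(2 * pi * t / p$period + p$phase) +
                   p$baseline)
    expect_equal(echo_curve(t + p$period, p), y, tolerance = 1e-9)
  }
})

test_that("envelope shrinks for positive AC and grows for negative AC", {
  t <- seq(0, 96, by = 0.1)
  win_max <- function(p) {
    y <- abs(echo_curve(t, p) - p$baseline)
    starts <- seq(0, 96 - p$period, by = p$period / 2)
    vapply(starts, function(s) max(y[t >= s & t <= s + p$period]), 0)
  }
  damped <- win_max(echo_params(1, 0.2, 24, 0.7, 0.3))
  expect_true(all(diff(damped) <= 1e-9))
  forced <- win_max(echo_params(1, -0.2, 24, 0.7, 0.3))
  expect_true(all(diff(forced) >= -1e-9))
})

test_that("trend curves evaluate their variants and degenerate correctly", {
  expect_equal(trend_curve(17, trend_params("linear", slope = 0,
                                            intercept = 3)), 3)
  expect_equal(trend_curve(c(0, 5, 50),
                           trend_params("exponential", scale = 1, rate = 0,
                                        offset = 1)), rep(2, 3))
  expect_equal(
    trend_curve(24, trend_params("echo_linear", amplitude = 1, ac_coef = 0,
                                 period = 24, phase = 0, baseline = 0,
                                 slope = 0.5)), 13)
  t <- seq(0, 48, 2)
  p <- list(amplitude = 1.3, ac_coef = 0.12, period = 22, phase = 0.4,
            baseline = -0.2)
  expect_equal(
    trend_curve(t, do.call(trend_params,
                           c(list("echo_linear"), p, slope = 0))),
    echo_curve(t, do.call(echo_params, setNames(p, NULL))))
  expect_equal(trend_curve(t, trend_params("linear", slope = 0,
                                           intercept = 2)), rep(2, 25))
})

test_that("AC classification follows the band rules with inclusive harmonic boundary", {
  expect_equal(as.character(classify_ac(0)), "harmonic")
  expect_equal(as.character(classify_ac(0.15)), "harmonic")
  expect_equal(as.character(classify_ac(-0.2)), "forced")
  expect_equal(as.character(classify_ac(0.2)), "damped")
  expect_equal(as.character(classify_ac(1)), "repressed")
  expect_equal(as.character(classify_ac(-1)), "overexpressed")
  expect_equal(as.character(classify_ac(0.5, 0.15, 1)), "damped")
})

test_that("AC categories partition the real line", {
  set.seed(7)
  g <- c(runif(500, -3, 3), -0.15, 0.15, -1, 1, 0)
  cats <- classify_ac(g)
  expect_false(anyNA(cats))
  expect_true(all(as.character(cats) %in% ac_categories()))
  # band membership is exclusive: recompute from the definition
  ref <- ifelse(abs(g) <= 0.15, "harmonic",
         ifelse(g > 0.15 & g < 1, "damped",
         ifelse(g < -0.15 & g > -1, "forced",
         ifelse(g >= 1, "repressed", "overexpressed"))))
  expect_equal(as.character(cats), ref)
})

test_that("peak time derives from phase and period", {
  expect_equal(peak_time(echo_params(1, 0, 24, 0)), 0)
  expect_equal(peak_time(echo_params(1, 0, 24, pi)), 12)
  expect_equal(peak_time(echo_params(2, 0.1, 20, pi / 2)), 15)
  expect_error(peak_time(list(amplitude = 0, ac_coef = 0, period = 24,
                              phase = 0, baseline = 0)),
               class = "circatrend_undefined_peak")
})

test_that("invalid parameters are rejected", {
  expect_error(echo_params(1, NA, 24, 0),
               class = "circatrend_invalid_parameter")
  expect_error(echo_params(1, 0, -2, 0),
               class = "circatrend_invalid_parameter")
  expect_error(echo_curve(c(-1, 2), echo_params(1, 0, 24, 0)),
               class = "circatrend_invalid_parameter")
  expect_error(classify_ac(Inf), class = "circatrend_invalid_parameter")
  expect_error(trend_params("linear", slope = 1),
               class = "circatrend_invalid_parameter")
})

test_that("negative amplitude folds into the phase", {
  p <- echo_params(-1.5, 0.1, 24, 0.5)
  expect_equal(p$amplitude, 1.5)
  expect_equal(p$phase, (0.5 + pi) %% (2 * pi))
  t <- seq(0, 48, 2)
  direct <- -1.5 * exp(-0.1 * t / 2) * cos(2 * pi * t / 24 + 0.5)
  expect_equal(echo_curve(t, p), direct, tolerance = 1e-12)
})
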