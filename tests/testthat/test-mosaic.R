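test_that("the trend library selects the generating model on noiseless curves", {
  t <- std_times()
  expect_equal(fit_trend_library(0.3 * t + 1, t)$best$model, "linear")
  expect_equal(fit_trend_library(0.8 * exp(0.05 * t) + 1, t)$best$model,
               "exponential")
  el <- fit_trend_library(
    echo_curve(t, echo_params(1, 0.05, 24, 1)) + 0.2 * t, t)
  expect_equal(el$best$model, "echo_linear")
  expect_equal(el$best$slope, 0.2, tolerance = 1e-3)
  # a pure oscillator: the extra slope parameter loses the BIC tie-break
  pure <- fit_trend_library(echo_curve(t, echo_params(1, 0.1, 24, 1)), t)
  expect_equal(pure$best$model, "echo")
  expect_equal(nrow(pure$candidates), 4)
})

test_that("noiseless parameters are recovered to 1e-3 for every library model", {
  t <- std_times()
  lin <- fit_trend_library(0.25 * t - 1, t)$best
  expect_equal(lin$slope, 0.25, tolerance = 1e-3)
  expect_equal(lin$baseline, -1, tolerance = 1e-3)
  ex <- fit_trend_library(1.5 * exp(-0.04 * t) + 0.5, t)$best
  expect_equal(ex$scale, 1.5, tolerance = 1e-3)
  expect_equal(ex$rate, -0.04, tolerance = 1e-3)
  expect_equal(ex$baseline, 0.5, tolerance = 1e-3)
  ec <- fit_trend_library(echo_curve(t, echo_params(0.8, -0.08, 26, 2.5, 0.3)),
                          t)$best
  expect_equal(ec$amplitude, 0.8, tolerance = 1e-3)
  expect_equal(ec$ac_coefficient, -0.08, tolerance = 1e-2)
  expect_equal(ec$period_h, 26, tolerance = 26e-3)
  el <- fit_trend_library(
    echo_curve(t, echo_params(1.2, 0.1, 22, 4)) - 0.15 * t + 1, t)$best
  expect_equal(el$slope, -0.15, tolerance = 1e-3)
  expect_equal(el$period_h, 22, tolerance = 22e-3)
  expect_equal(el$amplitude, 1.2, tolerance = 1e-2)
})

test_that("joint modeling recovers a shared oscillation from noiseless channels", {
  t <- std_times()
  y1 <- echo_curve(t, echo_params(1, 0.05, 24, 1))
  y2 <- echo_curve(t, echo_params(0.6, -0.05, 24, 1, 0.2))
  a <- wide_from_series(y1, y1 * 0.5 + 0.1)
  b <- wide_from_series(y2, y2)
  jf <- fit_joint_rhythms(a, b)
  jr <- jf$joint
  expect_equal(unique(round(jr$period_h, 6)),
               unique(round(jr$period_h, 6))[1]) # tau shared across channels
  expect_equal(jr$period_h[1], 24, tolerance = 24e-3)
  expect_true(all(jr$p_value < 1e-10))
  expect_true(all(jf$results$trend_label %in%
                    c("ECHO", "ECHO Linear", "ECHO Joint",
                      "ECHO Linear Joint")))
})

test_that("identical channels give joint estimates equal to independent fits", {
  set.seed(77)
  t <- std_times()
  y1 <- echo_curve(t, echo_params(1, 0.05, 24, 1)) + rnorm(75, 0, 0.2)
  y2 <- echo_curve(t, echo_params(0.9, 0, 22, 3)) + rnorm(75, 0, 0.2)
  m <- wide_from_series(y1, y2)
  jf <- fit_joint_rhythms(m, m)
  ind <- jf$independent
  for (ch in c("rna", "protein")) {
    for (fid in c("f01", "f02")) {
      j <- jf$joint[jf$joint$feature_id == fid & jf$joint$channel == ch, ]
      i <- ind[ind$feature_id == fid & ind$channel == ch, ]
      expect_equal(j$period_h, i$period_h, tolerance = 1e-6)
      expect_equal(j$rss, i$rss, tolerance = 1e-5)
    }
  }
  # equal information in both channels: joint never out-tests independent,
  # so no feature is labeled as joint-only
  expect_false(any(jf$results$trend_label %in%
                     c("ECHO Joint", "ECHO Linear Joint")))
})

test_that("a clean channel dominates a pure-noise channel in the joint fit", {
  set.seed(88)
  t <- std_times()
  y_rna <- echo_curve(t, echo_params(1.5, 0, 24, 1)) + rnorm(75, 0, 0.1)
  y_prot <- rnorm(75, 0, 5)
  jf <- fit_joint_rhythms(wide_from_series(y_rna), wide_from_series(y_prot))
  jr <- jf$joint
  w_rna <- jr$weight[jr$channel == "rna"]
  w_prot <- jr$weight[jr$channel == "protein"]
  expect_gt(w_rna, 10 * w_prot)
  expect_equal(jr$period_h[1], 24, tolerance = 0.02)
})

test_that("a zero-variance channel falls back to independent fits with a warning", {
  t <- std_times()
  y1 <- echo_curve(t, echo_params(1, 0, 24, 1)) + rep(c(0.1, -0.1), len = 75)
  a <- wide_from_series(y1)
  b <- wide_from_series(rep(3, 75))
  expect_warning(jf <- fit_joint_rhythms(a, b), "constant channel")
  expect_equal(nrow(jf$joint), 0)
  # labels still come from the independent fits
  expect_equal(jf$results$trend_label[jf$results$channel == "rna"], "ECHO")
})

test_that("trend labels follow the independent/joint precedence rules", {
  ind_row <- function(model, q, tau = 24, cat = "harmonic") {
    tibble::tibble(model = model, period_h = tau, ac_category = cat,
                   bh_q = q)
  }
  win <- c(20, 28)
  expect_equal(assign_trend_label(ind_row("echo", 0.001), NULL, win), "ECHO")
  expect_equal(assign_trend_label(ind_row("echo_linear", 0.001), NULL, win),
               "ECHO Linear")
  # independent misses, joint catches: the joint-only phenomenon
  expect_equal(
    assign_trend_label(ind_row("echo", 0.93),
                       ind_row("echo_joint", 2.75e-8), win),
    "ECHO Joint")
  expect_equal(
    assign_trend_label(ind_row("echo", 0.93),
                       ind_row("echo_linear_joint", 1e-4), win),
    "ECHO Linear Joint")
  expect_equal(assign_trend_label(ind_row("linear", 0.001), NULL, win),
               "Linear")
  expect_equal(assign_trend_label(ind_row("exponential", 0.001), NULL, win),
               "Exponential")
  expect_true(is.na(assign_trend_label(ind_row("echo", 0.5), NULL, win)))
  # out-of-window or extreme-AC oscillations are not circadian calls
  expect_true(is.na(assign_trend_label(ind_row("echo", 0.001, tau = 12),
                                       NULL, win)))
  expect_true(is.na(assign_trend_label(
    ind_row("echo", 0.001, cat = "repressed"), NULL, win)))
})

test_that("trend distribution tabulates counts and percentages", {
  d <- trend_distribution(c("ECHO", "ECHO", "Linear"))
  expect_equal(d$n[d$trend_label == "ECHO"], 2)
  expect_equal(d$pct[d$trend_label == "ECHO"], 200 / 3, tolerance = 1e-9)
  expect_equal(sum(d$n), 3)
  empty <- trend_distribution(character())
  expect_equal(sum(empty$n), 0)
  # per-channel tabulation from a results tibble
  res <- tibble::tibble(channel = c("rna", "rna", "protein"),
                        trend_label = c("ECHO", NA, "ECHO Joint"))
  d2 <- trend_distribution(res)
  expect_equal(sum(d2$n), 2) # unlabeled dropped
  expect_equal(d2$n[d2$channel == "protein" & d2$trend_label == "ECHO Joint"],
               1)
})
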