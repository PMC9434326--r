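test_that("presence filter keeps features at or above the cutoff", {
  cols <- paste0(rep(seq(0, 8, 2), each = 2), ".", rep(1:2, 5))
  v <- rbind(c(1, 2, 3, 4, 5, 6, 7, NA, NA, NA),   # 7/10 kept at 0.70
             c(1, 2, 3, 4, 5, 6, NA, NA, NA, NA),  # 6/10 removed
             rep(NA_real_, 10))                    # all-missing removed
  m <- make_wide(v, ids = c("keep", "drop", "empty"), cols = cols)
  out <- presence_filter(m, 0.7)
  expect_equal(out$feature_id, "keep")
  # empty input passes through
  expect_equal(nrow(presence_filter(m[0, ], 0.7)), 0)
})

test_that("raising the presence cutoff never adds features", {
  set.seed(21)
  v <- matrix(rnorm(30 * 75), 30)
  v[sample(length(v), 900)] <- NA
  m <- make_wide(v)
  kept <- sapply(seq(0.1, 1, by = 0.1),
                 function(f) nrow(presence_filter(m, f)))
  expect_true(all(diff(kept) <= 0))
})

test_that("imputation interpolates in time and falls back to the feature mean", {
  cols <- c("0.1", "2.1", "4.1")
  m <- make_wide(rbind(c(1, NA, 3), c(5, NA, NA), c(1, 2, 3)),
                 ids = c("interp", "meanfill", "full"), cols = cols)
  out <- impute_missing(m)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(1, 2, 3))
  expect_equal(unlist(out[2, -1], use.names = FALSE), c(5, 5, 5))
  # non-missing entries untouched; complete matrix is a fixed point
  expect_equal(out[3, ], m[3, ])
  expect_equal(impute_missing(out), out)
})

test_that("imputation interpolates within each replicate series separately", {
  cols <- c("0.1", "0.2", "2.1", "2.2", "4.1", "4.2")
  m <- make_wide(matrix(c(0, 10, NA, NA, 4, 30), 1), ids = "f", cols = cols)
  out <- impute_missing(m)
  expect_equal(unlist(out[1, -1], use.names = FALSE),
               c(0, 10, 2, 20, 4, 30))
})

test_that("z-scoring gives mean 0, sample SD 1, and zeros constant rows", {
  m <- wide_from_series(rnorm(75, 5, 3), rep(4, 75))
  out <- zscore_rows(m)
  r1 <- unlist(out[1, -1], use.names = FALSE)
  expect_equal(mean(r1), 0, tolerance = 1e-9)
  expect_equal(sd(r1), 1, tolerance = 1e-9)
  expect_equal(unlist(out[2, -1], use.names = FALSE), rep(0, 75))
  # sample-SD convention on a two-point series
  m2 <- make_wide(matrix(c(0, 10), 1), ids = "f", cols = c("0.1", "2.1"))
  expect_equal(unlist(zscore_rows(m2)[1, -1], use.names = FALSE),
               c(-0.70710678, 0.70710678), tolerance = 1e-7)
  expect_equal(zscore_rows(zscore_rows(m)), zscore_rows(m),
               tolerance = 1e-9)
})

test_that("linear detrending removes the OLS line and is idempotent", {
  t <- std_times()
  m <- wide_from_series(0.3 * t + 2, cos(2 * pi * t / 24))
  out <- detrend_linear(m)
  expect_equal(unlist(out[1, -1], use.names = FALSE), rep(0, 75),
               tolerance = 1e-10)
  # a full-cycle cosine has near-zero OLS slope: nearly unchanged
  expect_equal(unlist(out[2, -1], use.names = FALSE),
               unlist(m[2, -1], use.names = FALSE) -
                 mean(unlist(m[2, -1], use.names = FALSE)),
               tolerance = 0.05)
  expect_equal(detrend_linear(out), out, tolerance = 1e-9)
  # residual slope is zero
  slope <- unname(coef(lm(unlist(out[2, -1], use.names = FALSE) ~ t))[2])
  expect_equal(slope, 0, tolerance = 1e-10)
})

test_that("smoothing averages neighbours and renormalizes at boundaries", {
  cols <- c("0.1", "2.1", "4.1")
  m <- make_wide(rbind(c(0, 3, 0), c(4, 0, 0), c(2, 2, 2)), cols = cols)
  out <- smooth_rows(m, c(1, 2, 1))
  expect_equal(out$`2.1`[1], 1.5)          # (0 + 2*3 + 0)/4
  expect_equal(out$`0.1`[2], 8 / 3)        # (2*4 + 1*0)/3 at the boundary
  expect_equal(unlist(out[3, -1], use.names = FALSE), rep(2, 3))
  # fewer than 3 timepoints: identity
  m2 <- make_wide(matrix(c(1, 5), 1), cols = c("0.1", "2.1"))
  expect_equal(smooth_rows(m2), m2)
})

test_that("smoothing acts along time within each replicate series", {
  cols <- c("0.1", "0.2", "2.1", "2.2", "4.1", "4.2")
  m <- make_wide(matrix(c(0, 100, 3, 100, 0, 100), 1), cols = cols)
  out <- smooth_rows(m, c(1, 2, 1))
  expect_equal(out$`2.1`[1], 1.5)           # replicate 2 never mixes in
  expect_equal(out$`2.2`[1], 100)
})

test_that("paired presence filter intersects feature sets in order", {
  cols <- c("0.1", "2.1")
  a <- make_wide(matrix(1:6, 3), ids = c("a", "b", "c"), cols = cols)
  b <- make_wide(matrix(1:6, 3), ids = c("b", "c", "d"), cols = cols)
  out <- paired_presence_filter(a, b)
  expect_equal(out$a$feature_id, c("b", "c"))
  expect_equal(out$b$feature_id, c("b", "c"))
  same <- paired_presence_filter(a, a)
  expect_equal(same$a, a)
  d <- make_wide(matrix(1:2, 1), ids = "z", cols = cols)
  expect_warning(empty <- paired_presence_filter(a, d), "no features")
  expect_equal(nrow(empty$a), 0)
})

test_that("the full conditioning chain leaves no missing values", {
  set.seed(33)
  sim <- simulate_dataset(
    sim_spec(n_features = c(harmonic = 5, flat = 5), missing_rate = 0.1),
    seed = 5)
  out <- preprocess(sim$rna, detrend = TRUE, smooth = TRUE)
  expect_false(anyNA(out[-1]))
  expect_true(nrow(out) > 0)
  # after detrending (pre-smoothing) every feature has zero OLS slope
  dt <- preprocess(sim$rna, detrend = TRUE)
  d <- parse_design(dt)
  slopes <- apply(as.matrix(dt[-1]), 1, function(y) {
    unname(coef(lm(y ~ d$time))[2])
  })
  expect_equal(slopes, rep(0, nrow(dt)), tolerance = 1e-9)
})
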