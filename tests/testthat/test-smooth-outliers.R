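test_that("the corrected AIC follows its closed form", {
  # hand-computed: log(1/100) + (1 + 5/100) / (1 - 7/100)
  expect_equal(aicc(1, 5, 100), log(0.01) + 1.05 / 0.93)
  # monotone in rss at fixed edf
  expect_lt(aicc(0.5, 5, 100), aicc(1, 5, 100))
  # overfit penalty diverges as edf approaches n - 2
  expect_gt(aicc(1, 97.9, 100), aicc(1, 90, 100) + 100)
  expect_true(is.na(aicc(1, 98, 100)))
})

test_that("smoothing splines reproduce linear data at any smoothing", {
  t <- 1:40
  y <- 0.35 + 0.001 * t
  for (spar in c(-0.5, 0.5, 1.5)) {
    fit <- fit_spline(t, y, spar)
    expect_equal(fit$fitted, y, tolerance = 1e-7)
  }
  expect_error(fit_spline(1:5, rnorm(5), 0.5), "at least 8")
  expect_error(fit_spline(c(1, 3, 2, 4:10), rnorm(10), 0.5),
               "strictly increasing")
})

test_that("AICc selection is deterministic and adapts to signal", {
  set.seed(21)
  t <- 1:80
  # pure noise: low effective degrees of freedom in most seeds
  few <- 0
  for (i in 1:20) {
    fit <- select_spline(t, rnorm(80, 0.4, 0.01))
    if (fit$edf < 6) few <- few + 1
  }
  expect_gte(few, 18)  # >= 90%

  # noiseless seasonal curve: fit hugs the truth
  sp <- synthetic_site_spec(step = 3, seed = 1)
  g <- make_series(sp)
  fit <- select_spline(as.numeric(g$series$date - g$series$date[1]),
                       g$series$gcc)
  expect_lt(max(abs(fit$fitted - g$series$gcc)), 0.002)

  # repeated calls select the same smoothing
  y <- 0.4 + 0.05 * sin(t / 9) + rnorm(80, 0, 0.004)
  expect_identical(select_spline(t, y)$spar, select_spline(t, y)$spar)

  # moderate smoothing beats the raw spread on a noisy sine
  fit <- select_spline(t, y)
  expect_lt(sqrt(fit$rss / 80), sd(y))
})

test_that("the Laplace scale estimator has its closed form and scaling", {
  expect_equal(laplace_sd(c(-1, 1, -1, 1)), sqrt(2))
  r <- c(-0.3, 1.2, 0.4, -2, 0.05)
  expect_equal(laplace_sd(3 * r), 3 * laplace_sd(r))
  # consistency: large Laplace sample with scale b = 2 has SD -> 2*sqrt(2)
  set.seed(4)
  u <- runif(4e4) - 0.5
  x <- -2 * sign(u) * log(1 - 2 * abs(u))
  expect_equal(laplace_sd(x), 2 * sqrt(2), tolerance = 0.05)
})

test_that("an injected gross outlier is flagged", {
  sp <- synthetic_site_spec(step = 3, noise = 0.004, seed = 3)
  g <- make_series(sp)
  t <- as.numeric(g$series$date - g$series$date[1])
  y <- g$series$gcc
  base <- detect_outliers(t, y)
  y_inj <- y
  y_inj[60] <- y[60] - 10 * 0.004  # dropped by 10x the noise scale
  fit <- detect_outliers(t, y_inj)
  expect_equal(fit$flags[60], 1L)
  # relative to the clean run, the injection adds no other flags
  expect_length(setdiff(which(fit$flags == 1L),
                        union(60L, which(base$flags == 1L))), 0)

  # a noiseless series carries no flaggable outliers at all
  clean <- detect_outliers(t, trajectory_gcc(sp, g$series$doy))
  expect_equal(sum(clean$flags), 0L)
})

test_that("flagging is asymmetric: 2 SD below, 4 SD above", {
  set.seed(12)
  t <- 1:100
  y <- 0.4 + rlap(100, 0.004)
  fit0 <- detect_outliers(t, y)
  sig <- canopygcc::laplace_sd(y - fit0$fitted)
  y2 <- y
  y2[30] <- fit0$fitted[30] + 3 * sig  # +3 SD: inside the 4 SD band
  y2[70] <- fit0$fitted[70] - 3 * sig  # -3 SD: beyond the 2 SD band
  fit <- detect_outliers(t, y2)
  expect_equal(fit$flags[30], 0L)
  expect_equal(fit$flags[70], 1L)
})

test_that("removing flagged points leaves the smoothed curve stable", {
  set.seed(17)
  sp <- synthetic_site_spec(step = 3, noise = 0.005, outlier_frac = 0.03,
                            seed = 17)
  g <- make_series(sp)
  t <- as.numeric(g$series$date - g$series$date[1])
  fit <- detect_outliers(t, g$series$gcc)
  keep <- fit$flags == 0L
  refit <- detect_outliers(t[keep], g$series$gcc[keep])
  # the curve moves by far less than the residual scale (the rerun may
  # trim a few extra noise-tail points, because with the gross outliers
  # gone the conservative scale estimate tightens)
  expect_lt(max(abs(refit$fitted - fit$fitted[keep])), fit$sigma)
  # and the final refit never fits the kept points worse than the
  # pre-rejection spline did
  rmse_first <- sqrt(mean((g$series$gcc[keep] -
                             predict(fit, t)[keep])^2))
  expect_lte(fit$rmse, rmse_first + 1e-12)
})

test_that("interpolation flags mark the interior of long gaps only", {
  dates <- as.Date("2015-01-01") + seq(0, 120, by = 3)
  obs <- rep(TRUE, length(dates))
  expect_equal(sum(interpolation_flag(dates, obs)), 0)

  # 21-day hole: interior windows flagged
  gap <- dates > as.Date("2015-02-01") & dates < as.Date("2015-02-22")
  flags <- interpolation_flag(dates, !gap)
  expect_true(all(flags[gap] == 1L))
  expect_true(all(flags[!gap] == 0L))

  # a 13-day spacing stays below the 14-day threshold
  d13 <- as.Date("2015-01-01") + c(0, 13, 26)
  expect_equal(interpolation_flag(d13, rep(TRUE, 3)), rep(0L, 3))
  d14 <- as.Date("2015-01-01") + c(0, 7, 21)
  expect_equal(interpolation_flag(d14, c(TRUE, TRUE, TRUE)), rep(0L, 3))
  expect_equal(interpolation_flag(d14, c(TRUE, FALSE, TRUE)),
               c(0L, 1L, 0L))
})

test_that("smoothing a summary fills every smoothed column", {
  # mid-season snow drives Gcc from ~0.45 to the achromatic 1/3
  sp <- synthetic_site_spec(step = 3, noise = 0.004, seed = 23,
                            snow_days = c(152, 155))
  s <- summary_from_series(make_series(sp)$series, step = 3)
  for (col in c("smooth_gcc_mean", "smooth_gcc_90", "smooth_rcc_50")) {
    expect_true(all(!is.na(s[[col]])))
  }
  expect_true(all(s$smooth_ci_gcc_mean > 0))
  rmse <- attr(s, "spline_rmse")
  expect_true(all(rmse[c("gcc_mean", "gcc_50")] > 0))
  # snow dip far below the curve is flagged
  expect_true(all(s$outlierflag_gcc_mean[s$doy %in% c(152, 155)] == 1L))
})
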