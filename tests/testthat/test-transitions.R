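test_that("PELT finds nothing in constant signals and the obvious step", {
  expect_equal(pelt(rep(0.5, 50), 0.5, 14), integer(0))
  expect_equal(pelt(rnorm(20), 0.5, 14), integer(0))  # n < 2 * minseg

  set.seed(41)
  x <- c(rep(0, 30), rep(1, 30)) + rnorm(60, 0, 0.05)
  z <- (x - mean(x)) / sd(x)
  expect_equal(pelt(z, 0.5, 14), 30L)
})

test_that("PELT equals the optimal-partitioning dynamic program", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- rnorm(n) +
      rep(rnorm(3, 0, 2), length.out = n, each = ceiling(n / 3))
    minseg <- sample(2:6, 1)
    beta <- runif(1, 0.2, 3)
    expect_identical(pelt(x, beta, minseg),
                     oracle_segment_dp(x, beta, minseg))
  }
})

smoothed_fixture <- function(seed, noise = 0, ...) {
  sp <- synthetic_site_spec(step = 3, noise = noise, seed = seed, ...)
  g <- make_series(sp)
  s <- summary_from_series(g$series, step = 3)
  list(spec = sp, gen = g, summary = s)
}

test_that("a single season yields one rising and one falling stage", {
  fx <- smoothed_fixture(2)
  sm <- fx$summary$smooth_gcc_50
  cps <- pelt((sm - mean(sm)) / sd(sm), 0.5, 5)
  stages <- extract_stages(fx$summary$date, sm, cps,
                           attr(fx$summary, "spline_rmse")[["gcc_50"]])
  expect_equal(stages$direction, c("rising", "falling"))
  expect_true(all(stages$amplitude > 0))
  # rising precedes falling, sharing the seasonal peak
  expect_lt(stages$start_idx[1], stages$start_idx[2])
  expect_equal(stages$max_gcc[1], stages$max_gcc[2], tolerance = 1e-6)
})

test_that("a bimodal year yields two cycles", {
  fx <- smoothed_fixture(
    5, amplitude = 0.08, spring_mid = 70, spring_rate = 0.2,
    autumn_mid = 130, autumn_rate = 0.2,
    second_pulse = list(amplitude = 0.08, spring_mid = 230,
                        spring_rate = 0.2, autumn_mid = 300,
                        autumn_rate = 0.2))
  td <- extract_transition_dates(fx$summary)
  td50 <- td[td$gcc_value == "gcc_50", ]
  expect_equal(sum(td50$direction == "rising"), 2)
  expect_equal(sum(td50$direction == "falling"), 2)
})

test_that("flat series produce no stages", {
  dates <- as.Date("2015-01-01") + seq(0, 363, 3)
  sm <- rep(0.36, length(dates)) + 0.001 * sin(seq_along(dates) / 9)
  stages <- extract_stages(dates, sm, integer(0), rmse = 0.002)
  expect_equal(nrow(stages), 0)
})

test_that("threshold values obey the amplitude identity", {
  fx <- smoothed_fixture(3, noise = 0.004)
  td <- extract_transition_dates(fx$summary)
  expect_gt(nrow(td), 0)
  for (pct in c(10, 25, 50)) {
    expect_equal(td[[paste0("threshold_", pct)]],
                 td$min_gcc + pct / 100 * (td$max_gcc - td$min_gcc),
                 tolerance = 1e-9)
  }
  # worked threshold example: min 0.35, max 0.45 -> 25% at 0.375
  stage <- tibble::tibble(direction = "rising", start_idx = 1L,
                          end_idx = 3L, min_gcc = 0.35, max_gcc = 0.45,
                          amplitude = 0.10)
  out <- canopygcc:::stage_transition_dates(
    stage, as.Date("2015-01-01") + 0:2, c(0.35, 0.40, 0.45), 0,
    as.Date(character(0)), 1)
  expect_equal(out$threshold_25, 0.375)
})

test_that("transition dates are ordered within stages", {
  fx <- smoothed_fixture(13, noise = 0.004)
  td <- extract_transition_dates(fx$summary)
  ris <- td[td$direction == "rising", ]
  expect_true(all(ris$transition_10 <= ris$transition_25 &
                    ris$transition_25 <= ris$transition_50))
  fal <- td[td$direction == "falling", ]
  expect_true(all(fal$transition_50 <= fal$transition_25 &
                    fal$transition_25 <= fal$transition_10))
  for (pct in c(10, 25, 50)) {
    expect_true(all(
      td[[paste0("transition_", pct, "_lower_ci")]] <=
        td[[paste0("transition_", pct)]] &
        td[[paste0("transition_", pct)]] <=
        td[[paste0("transition_", pct, "_upper_ci")]]))
  }
})

test_that("zero-noise confidence intervals sit at the sampling floor", {
  fx <- smoothed_fixture(2)  # noiseless
  td <- extract_transition_dates(fx$summary)
  row <- td[td$direction == "rising" & td$gcc_value == "gcc_50", ]
  # 3-day product: the floor is the neighbouring observation, +/- 3 d
  expect_equal(as.numeric(row$transition_50 - row$transition_50_lower_ci),
               3)
  expect_equal(as.numeric(row$transition_50_upper_ci - row$transition_50),
               3)
})

test_that("noiseless 3-day sampling recovers the analytic 50% crossing", {
  fx <- smoothed_fixture(7)
  td <- extract_transition_dates(fx$summary)
  truth <- fx$gen$truth$transitions
  origin <- as.Date("2014-12-31")
  for (d in c("rising", "falling")) {
    est <- td$transition_50[td$direction == d & td$gcc_value == "gcc_50"]
    true_date <- origin + truth$transition_50[truth$direction == d]
    expect_lte(abs(as.numeric(est - true_date)), 3)
  }
})

test_that("normalising by stage extrema maps the smooth onto [0, 1]", {
  fx <- smoothed_fixture(4, noise = 0.003)
  td <- extract_transition_dates(fx$summary)
  row <- td[td$direction == "rising" & td$gcc_value == "gcc_mean", ]
  sm <- fx$summary$smooth_gcc_mean
  z <- (sm - row$min_gcc) / (row$max_gcc - row$min_gcc)
  expect_gte(min(z), -0.05)
  expect_lte(max(z), 1.05)
})

test_that("the transition-date dialect round-trips", {
  fx <- smoothed_fixture(3, noise = 0.004)
  td <- extract_transition_dates(fx$summary)
  expect_equal(nrow(td), 8)  # 1 rising + 1 falling stage x 4 statistics
  p1 <- tempfile(fileext = ".csv")
  write_transitions(td, p1)
  lines <- readLines(p1)
  expect_equal(sum(grepl("^#", lines)), 16)
  expect_match(lines[17], "^sitename,veg_type,roi_id,direction,gcc_value")
  expect_true(any(grepl("^# Spline RMSE gcc_90", lines)))
  back <- read_transitions(p1)
  expect_true(all(back$direction %in% c("rising", "falling")))
  p2 <- tempfile(fileext = ".csv")
  write_transitions(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # malformed dates are a format error
  bad <- sub("^(series,XX,0001,rising,gcc_mean,)[0-9-]+",
             "\\12015-13-99", readLines(p1))
  writeLines(bad, p2)
  expect_error(read_transitions(p2), "date")
  unlink(c(p1, p2))
})
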