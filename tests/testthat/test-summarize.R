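test_that("QC filters use strict inequalities at documented thresholds", {
  rec <- fake_roistats(
    date = rep(as.Date("2015-06-01"), 5),
    local_std_time = sprintf("%02d:00:00", 8:12),
    solar_elev = c(9.9, 45, 45, 45, 10),
    r = c(100, 222, 200, 33, 100),
    g = c(100, 222, 265, 33, 100),
    b = c(100, 222, 200, 33, 100))
  out <- qc_pass(rec)
  expect_equal(out$qc_pass, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$qc_reason[1], "low sun")     # 9.9 < 10
  expect_equal(out$qc_reason[2], "too bright")  # 666 > 665
  expect_true(is.na(out$qc_reason[3]))          # 665 passes (strict)
  expect_equal(out$qc_reason[4], "too dark")    # 99 < 100
  expect_true(is.na(out$qc_reason[5]))          # elev 10, sum 300 pass
})

test_that("3-day windows sit on the fixed doy grid", {
  w <- bin_windows(2015, 3)
  expect_equal(w$doy[1:3], c(2L, 5L, 8L))
  expect_equal(w$days[[1]], 1:3)
  expect_equal(w$doy[nrow(w)], 365L)
  expect_equal(w$days[[nrow(w)]], c(364L, 365L))  # non-leap: 2 days

  wl <- bin_windows(2016, 3)
  expect_equal(wl$days[[nrow(wl)]], c(364L, 365L, 366L))  # leap: 3 days
  expect_equal(nrow(wl), length(seq(2, 365, 3)))

  expect_equal(nrow(bin_windows(2015, 1)), 365)
  expect_equal(nrow(bin_windows(2016, 1)), 366)
})

test_that("every member day belongs to exactly one window", {
  for (yr in c(2015, 2016)) {
    days <- sort(unlist(bin_windows(yr, 3)$days))
    expect_equal(days, seq_len(if (yr == 2016) 366 else 365))
  }
})

test_that("midday selection picks the image nearest noon, earlier on ties", {
  rec <- fake_roistats(
    date = rep(as.Date("2015-06-02"), 3),
    local_std_time = c("11:30:00", "12:01:00", "13:00:00"),
    solar_elev = 50, r = 100, g = 110, b = 90)
  expect_equal(select_midday(rec, "2015-06-02")$local_std_time, "12:01:00")

  tie <- fake_roistats(
    date = rep(as.Date("2015-06-02"), 2),
    local_std_time = c("11:59:00", "12:01:00"),
    solar_elev = 50, r = 100, g = 110, b = 90)
  expect_equal(select_midday(tie, "2015-06-02")$local_std_time, "11:59:00")

  expect_null(select_midday(rec, "2015-06-03"))
})

test_that("window summaries aggregate per-image values", {
  # ten images inside one 3-day window, gcc = 0.31 .. 0.40
  g_target <- seq(0.31, 0.40, by = 0.01)
  total <- 300
  rec <- fake_roistats(
    date = as.Date("2015-01-01") + rep(0:1, each = 5),
    local_std_time = sprintf("%02d:00:00", rep(8:12, 2)),
    solar_elev = 50,
    r = (1 - g_target) / 2 * total, g = g_target * total,
    b = (1 - g_target) / 2 * total)
  s <- summarize_roistats(rec, step = 3, smooth = FALSE)
  row <- s[s$doy == 2, ]
  expect_equal(row$image_count, 10L)
  expect_equal(row$gcc_mean, mean(g_target))
  expect_equal(row$gcc_90, oracle_quantile(g_target, 0.9))
  expect_equal(row$gcc_50, oracle_quantile(g_target, 0.5))
  expect_true(row$gcc_50 <= row$gcc_75 && row$gcc_75 <= row$gcc_90)
  # midday image: closest to noon on the middle day (Jan 2)
  expect_equal(row$midday_filename,
               format_image_filename("fake", as.Date("2015-01-02"),
                                     "12:00:00"))
  # empty windows are NA rows with image_count 0
  empty <- s[s$doy == 8, ]
  expect_equal(empty$image_count, 0L)
  expect_true(is.na(empty$gcc_mean))
  expect_true(is.na(empty$midday_filename))
})

test_that("a single valid image yields NA spread statistics", {
  rec <- fake_roistats(date = as.Date("2015-06-01"),
                       local_std_time = "12:00:00",
                       solar_elev = 50, r = 90, g = 120, b = 80)
  s <- summarize_roistats(rec, step = 1, smooth = FALSE)
  row <- s[s$image_count == 1L, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$gcc_mean, rec$gcc)
  expect_true(is.na(row$gcc_std))
})

test_that("midday statistics are reported even when QC empties a window", {
  rec <- fake_roistats(date = as.Date("2015-06-01"),
                       local_std_time = "12:00:00",
                       solar_elev = 5, r = 90, g = 120, b = 80)  # low sun
  s <- summarize_roistats(rec, step = 1, smooth = FALSE)
  row <- s[s$date == as.Date("2015-06-01"), ]
  expect_equal(row$image_count, 0L)
  expect_true(is.na(row$gcc_mean))
  expect_equal(row$midday_gcc, rec$gcc)
})

test_that("snow flags are looked up by midday filename", {
  rec <- fake_roistats(date = as.Date("2015-01-15"),
                       local_std_time = "12:00:00",
                       solar_elev = 20, r = 100, g = 100, b = 100)
  snow <- data.frame(filename = rec$filename, code = 5L)
  s <- summarize_roistats(rec, step = 1, snow = snow, smooth = FALSE)
  expect_equal(s$snowflag[s$date == as.Date("2015-01-15")], 5L)
  expect_true(all(is.na(s$snowflag[s$date != as.Date("2015-01-15")])))
})

test_that("window image counts sum to the QC-passing record count", {
  set.seed(8)
  n <- 300
  dates <- sort(sample(as.Date("2015-01-01") + 0:364, n, replace = TRUE))
  rec <- fake_roistats(
    date = dates,
    local_std_time = sprintf("%02d:%02d:00", sample(6:18, n, TRUE),
                             sample(0:59, n, TRUE)),
    solar_elev = runif(n, 0, 70),
    r = runif(n, 20, 90), g = runif(n, 20, 120), b = runif(n, 20, 90))
  s <- summarize_roistats(rec, step = 3, smooth = FALSE)
  expect_equal(sum(s$image_count), sum(qc_pass(rec)$qc_pass))
})

test_that("the summary dialect round-trips with its metadata block", {
  set.seed(9)
  sp <- synthetic_site_spec(step = 3, noise = 0.004, seed = 9)
  s <- summary_from_series(make_series(sp)$series, step = 3)
  p1 <- tempfile(fileext = ".csv")
  write_summary(s, p1)
  lines <- readLines(p1)
  expect_equal(sum(grepl("^#", lines)), 24)
  expect_match(lines[12], "^# Aggregation Period: 3")
  expect_match(lines[13], "^# Solar Elevation Min: 10")
  expect_match(lines[16], "^# ROI Brightness Min: 100")
  expect_match(lines[17], "^# ROI Brightness Max: 665")
  expect_match(lines[25], "^date,year,doy,image_count")
  back <- read_summary(p1)
  expect_equal(attr(back, "step"), 3L)
  p2 <- tempfile(fileext = ".csv")
  write_summary(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # smoothed values are present on every row, including missing dates
  expect_true(all(!is.na(back$smooth_gcc_mean)))
  unlink(c(p1, p2))
})
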