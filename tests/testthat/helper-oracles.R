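# Independent oracles, written from first principles so they share no code
# with the implementation they check.

# percentile by hand: sort, locate the fractional rank h = (n-1)p + 1, and
# interpolate linearly between the two closest order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# population standard deviation by the definition
oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

# optimal partitioning under the Gaussian mean-change cost: plain O(n^2)
# dynamic program, no pruning
oracle_segment_dp <- function(x, beta, minseg) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segrss <- function(s, t) { # segment s..t, 1-based inclusive
    len <- t - s + 1
    sx <- cs[t + 1] - cs[s]
    (cs2[t + 1] - cs2[s]) - sx^2 / len
  }
  f <- rep(Inf, n + 1)
  f[1] <- -beta
  prev <- integer(n + 1)
  for (t in seq_len(n)) {
    if (t < minseg) next
    for (s in 0:(t - minseg)) {
      if (!is.finite(f[s + 1])) next
      v <- f[s + 1] + segrss(s + 1, t) + beta
      if (v < f[t + 1]) {
        f[t + 1] <- v
        prev[t + 1] <- s
      }
    }
  }
  if (!is.finite(f[n + 1])) return(integer(0))
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

# Laplace deviates with standard deviation sd, by inverse transform
rlap <- function(n, sd) {
  b <- sd / sqrt(2)
  u <- runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

# write a small single-band 8-bit TIFF mask (values 0-255)
write_test_mask <- function(values, path = tempfile(fileext = ".tif")) {
  tiff::writeTIFF(values / 255, path, bits.per.sample = 8)
  path
}

# uniform RGB JPEG with the given DN triplet, under a timestamped name
write_test_jpeg <- function(dir, sitename, date, time, rgb, h = 10, w = 12) {
  img <- array(rep(rgb / 255, each = h * w), dim = c(h, w, 3))
  path <- file.path(dir, format_image_filename(sitename, date, time))
  jpeg::writeJPEG(img, path, quality = 1)
  path
}

# minimal all-image record table for QC / aggregation tests
fake_roistats <- function(date, local_std_time, solar_elev, r, g, b,
                          filename = NULL) {
  n <- length(date)
  if (is.null(filename)) {
    filename <- format_image_filename("fake", as.Date(date), local_std_time)
  }
  cc <- chromatic_coords(r, g, b)
  tb <- tibble::tibble(
    date = as.Date(date), local_std_time = local_std_time,
    doy = as.integer(strftime(as.Date(date), "%j")), filename = filename,
    solar_elev = solar_elev, exposure = NA_real_, mask_index = 1L,
    gcc = cc$gcc, rcc = cc$rcc)
  for (ch in c("r", "g", "b")) {
    v <- get(ch)
    tb[[paste0(ch, "_mean")]] <- v
    tb[[paste0(ch, "_std")]] <- 0
    for (q in c("5", "10", "25", "50", "75", "90", "95")) {
      tb[[paste0(ch, "_", q, "_qtl")]] <- v
    }
  }
  tb$r_g_cor <- NA_real_
  tb$g_b_cor <- NA_real_
  tb$b_r_cor <- NA_real_
  canopygcc:::new_roistats(tb, sitename = "fake", veg_type = "DB",
                           roi_id = "0001", lat = 42.5, lon = -72.2,
                           elevation = 340, utc_offset = -5)
}
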