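#' Fit the camera sensor response function
#'
#' The response of the imaging process is summarised by the exponential
#' relationship `y = a * exp(b * x) + e`, where `x` is the natural log of
#' exposure (integration time times irradiance) and `y` the digital
#' number output. The fit is performed as a linear regression of `ln y`
#' on `x`; points approaching saturation (DN above `saturation`) are
#' excluded, since they bend away from the exponential.
#'
#' @param x Natural log of exposure.
#' @param y Digital number output (must be positive and below 255).
#' @param saturation DN above which points are excluded from the fit
#'   (default 220).
#' @return A `response_fit` object with elements `a`, `b`, `fitted`,
#'   `residuals` (DN scale, all points), `rmse`, and `n_used`.
#' @export
fit_response <- function(x, y, saturation = 220) {
  stopifnot(length(x) == length(y))
  if (any(y <= 0 | y >= 255)) {
    stop("digital numbers must lie in (0, 255)", call. = FALSE)
  }
  use <- y <= saturation
  if (sum(use) < 3) stop("need at least 3 unsaturated points", call. = FALSE)
  fit <- stats::lm(log(y[use]) ~ x[use])
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  fitted <- a * exp(b * x)
  res <- y - fitted
  structure(
    list(a = a, b = b, x = x, y = y, used = use, fitted = fitted,
         residuals = res, rmse = sqrt(mean(res[use]^2)),
         n_used = sum(use)),
    class = "response_fit"
  )
}

#' @export
print.response_fit <- function(x, ...) {
  cat("<response_fit> y = a * exp(b * x):  a = ", signif(x$a, 6),
      ", b = ", signif(x$b, 6), "  (", x$n_used, " points, rmse = ",
      signif(x$rmse, 4), " DN)\n", sep = "")
  invisible(x)
}

#' Reference-panel analysis configuration
#'
#' @param min_solar_elev Minimum solar elevation in degrees (default 5).
#' @param brightness_window Inclusive bounds on the panel channel-mean DN
#'   sum (default `c(200, 565)`).
#' @return A `panel_config` list.
#' @export
panel_config <- function(min_solar_elev = 5,
                         brightness_window = c(200, 565)) {
  stopifnot(brightness_window[1] < brightness_window[2])
  structure(list(min_solar_elev = min_solar_elev,
                 brightness_window = brightness_window),
            class = "panel_config")
}

#' Colour-balance stability of a grey reference panel
#'
#' A grey reflectance panel in the camera field of view should have a
#' constant chromatic signature; the standard deviation of its Gcc across
#' a year therefore measures the stability of the image colour balance
#' under changing weather and illumination. Records are filtered to solar
#' elevation above `min_solar_elev` and panel brightness inside the
#' configured window before the SD is taken.
#'
#' @param records All-image records for a reference-panel ROI (needs
#'   `solar_elev`, `r_mean`, `g_mean`, `b_mean`, `gcc`).
#' @param cfg A [panel_config()].
#' @return A one-row tibble: `sd_gcc` (sample SD of panel Gcc), `n_used`,
#'   and `ci_halfwidth` (`2.5 * sd_gcc`, a conservative 99% interval
#'   half-width for individual Gcc values).
#' @export
panel_stability <- function(records, cfg = panel_config()) {
  total <- records$r_mean + records$g_mean + records$b_mean
  keep <- records$solar_elev > cfg$min_solar_elev &
    total >= cfg$brightness_window[1] & total <= cfg$brightness_window[2]
  n <- sum(keep)
  if (n < 10) {
    stop("fewer than 10 panel records pass the filters", call. = FALSE)
  }
  sd_gcc <- stats::sd(records$gcc[keep])
  tibble::tibble(sd_gcc = sd_gcc, n_used = n, ci_halfwidth = 2.5 * sd_gcc)
}

#' Rescale a greenness series to relative Gcc
#'
#' Linearly rescales a seasonal Gcc series so that the dormant-season mean
#' (day of year after 290 or before 110) maps to 0 and the peak-summer
#' mean (day of year after 150 and before 180) maps to 1. Absolute Gcc
#' differs between cameras viewing the same canopy; the relative scale
#' makes their seasonal trajectories directly comparable.
#'
#' @param data Data frame with a day-of-year column and a Gcc column.
#' @param doy,gcc Column names (defaults `"doy"`, `"gcc"`).
#' @return The input tibble with an appended `rel_gcc` column.
#' @export
relative_gcc <- function(data, doy = "doy", gcc = "gcc") {
  d <- data[[doy]]
  g <- data[[gcc]]
  dormant <- (d > 290 | d < 110) & !is.na(g)
  peak <- (d > 150 & d < 180) & !is.na(g)
  if (sum(dormant) < 3 || sum(peak) < 3) {
    stop("need at least 3 points in both the dormant (doy > 290 or < 110) ",
         "and peak (doy 150-180) windows", call. = FALSE)
  }
  lo <- mean(g[dormant])
  hi <- mean(g[peak])
  if (hi == lo) stop("zero seasonal amplitude; cannot rescale", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(data), rel_gcc = (g - lo) / (hi - lo))
}
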