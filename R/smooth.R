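#' Corrected AIC for smoothing-parameter selection
#'
#' The improved AIC for nonparametric regression, which replaces the
#' parameter count of the classical criterion with the effective degrees
#' of freedom (edf) of the linear smoother and carries a finite-sample
#' correction:
#' \deqn{AICc = \log(RSS/n) + (1 + edf/n) / (1 - (edf + 2)/n)}
#' The criterion diverges as `edf` approaches `n - 2`, penalising
#' near-interpolating fits.
#'
#' @param rss Residual sum of squares of the fit.
#' @param edf Effective degrees of freedom (trace of the smoother matrix).
#' @param n Number of observations; must exceed `edf + 2`.
#' @return The criterion value (`NA` when `n <= edf + 2`, which excludes
#'   the candidate).
#' @export
aicc <- function(rss, edf, n) {
  ifelse(n > edf + 2,
         log(rss / n) + (1 + edf / n) / (1 - (edf + 2) / n),
         NA_real_)
}

# spar grid spanning near-interpolation to the linear (edf = 2) limit;
# fixed so spline selection is deterministic.
SPAR_GRID <- seq(2, -1, length.out = 30)

#' Fit a cubic smoothing spline at a fixed smoothing level
#'
#' @param t Numeric time axis (days), strictly increasing.
#' @param y Response (e.g. Gcc), no missing values.
#' @param spar Smoothing parameter on the log-lambda scale used by
#'   [stats::smooth.spline()].
#' @return A list with the fitted `smooth.spline` object, `fitted` values
#'   at `t`, `edf` (trace of the smoother matrix), and `rss`.
#' @export
fit_spline <- function(t, y, spar) {
  if (length(t) < 8) {
    stop("need at least 8 observations to fit the smoothing spline",
         call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  fit <- stats::smooth.spline(t, y, spar = spar, all.knots = TRUE,
                              keep.data = FALSE, cv = FALSE)
  fitted <- stats::predict(fit, t)$y
  list(spline = fit, fitted = fitted, edf = fit$df,
       rss = sum((y - fitted)^2), spar = spar)
}

#' Select the smoothing spline by corrected AIC
#'
#' Fits a family of cubic smoothing splines over a fixed grid of 30
#' smoothing values spanning near-interpolation to a near-linear fit, and
#' returns the one minimising [aicc()]. Deterministic given the grid; ties
#' go to the smoother fit. If every candidate is undefined (tiny n), the
#' maximum-smoothing fit is returned with a warning.
#'
#' @inheritParams fit_spline
#' @return As [fit_spline()], with the selected `spar`.
#' @export
select_spline <- function(t, y) {
  best <- NULL
  best_score <- Inf
  n <- length(y)
  for (s in SPAR_GRID) {  # grid runs smoothest first, so ties stay smooth
    cand <- suppressWarnings(fit_spline(t, y, s))
    score <- aicc(cand$rss, cand$edf, n)
    if (!is.na(score) && score < best_score) {
      best <- cand
      best_score <- score
    }
  }
  if (is.null(best)) {
    warning("no AICc-admissible spline; falling back to maximum smoothing",
            call. = FALSE)
    best <- suppressWarnings(fit_spline(t, y, SPAR_GRID[1]))
  }
  best
}

#' Laplace-model standard deviation of residuals
#'
#' The residual scale is estimated under a Laplace (double-exponential)
#' model: the maximum-likelihood scale is the mean absolute residual `b`,
#' and the standard deviation of a Laplace variate with scale `b` is
#' `sqrt(2) * b`. A heavy-tailed residual model is appropriate because
#' weather and snow produce occasional large greenness excursions.
#'
#' @param residuals Numeric residual vector (length >= 2).
#' @return The Laplace-based standard deviation (0 when all residuals are
#'   zero, in which case no outliers are flaggable).
#' @export
laplace_sd <- function(residuals) {
  stopifnot(length(residuals) >= 2)
  sqrt(2) * mean(abs(residuals))
}

#' Outlier-detection configuration
#'
#' Points more than `k_upper` standard deviations above, or `k_lower`
#' standard deviations below, the spline are flagged (standard deviations
#' from [laplace_sd()]). The asymmetry filters downward excursions (snow,
#' fog, bad exposures) more aggressively, since they are larger and more
#' common than upward ones.
#'
#' @param k_upper Upward threshold in residual SDs (default 4).
#' @param k_lower Downward threshold in residual SDs (default 2).
#' @param max_iter Maximum number of flagging passes (default 20).
#' @param min_sigma Smallest residual SD (in Gcc units) at which flagging
#'   is attempted (default 1e-4). Below this the series is at the
#'   resolution of 8-bit quantisation and residual structure reflects
#'   spline approximation error, not observation noise, so no outliers
#'   are flaggable.
#' @return An `outlier_config` list.
#' @export
outlier_config <- function(k_upper = 4, k_lower = 2, max_iter = 20,
                           min_sigma = 1e-4) {
  stopifnot(k_upper > 0, k_lower > 0, max_iter >= 1, min_sigma >= 0)
  structure(list(k_upper = k_upper, k_lower = k_lower,
                 max_iter = max_iter, min_sigma = min_sigma),
            class = "outlier_config")
}

#' Iterative spline-based outlier detection
#'
#' Repeats: fit the AICc-selected spline to the unflagged points, estimate
#' the residual SD under the Laplace model from the residuals of all
#' points about the current spline (keeping the threshold conservative in
#' the presence of gross outliers), and flag points more than `k_upper`
#' SD above or `k_lower` SD below the spline. Flags accumulate
#' across passes; iteration stops when a pass adds no flags or after
#' `max_iter` passes, and the spline is then refit one final time on the
#' unflagged points.
#'
#' @inheritParams fit_spline
#' @param cfg An [outlier_config()].
#' @return A `gcc_spline` object: fields `t`, `y`, `flags` (0/1 per
#'   point), `fitted` (final fit at `t`), `edf`, `spar`, `sigma`
#'   (Laplace-based residual SD of the final fit), `rmse`, and
#'   `ci_halfwidth` (`1.96 * sigma`).
#' @export
detect_outliers <- function(t, y, cfg = outlier_config()) {
  n <- length(y)
  flags <- rep(0L, n)
  for (iter in seq_len(cfg$max_iter)) {
    keep <- flags == 0L
    fit <- select_spline(t[keep], y[keep])
    pred <- stats::predict(fit$spline, t)$y
    # scale from the residuals of every point (flagged ones included):
    # already-identified outliers keep the threshold conservative, so the
    # noise tail of clean data is not progressively eaten away
    sigma <- laplace_sd(y - pred)
    if (sigma < cfg$min_sigma) break
    new_flag <- keep &
      (y > pred + cfg$k_upper * sigma | y < pred - cfg$k_lower * sigma)
    if (!any(new_flag)) break
    flags[new_flag] <- 1L
    if (sum(flags) > n / 2) {
      stop("more than half of the points flagged as outliers; ",
           "data quality too poor to smooth", call. = FALSE)
    }
  }
  final_spline_fit(t, y, flags)
}

final_spline_fit <- function(t, y, flags) {
  keep <- flags == 0L
  fit <- select_spline(t[keep], y[keep])
  pred <- stats::predict(fit$spline, t)$y
  res <- y[keep] - pred[keep]
  sigma <- laplace_sd(res)
  structure(
    list(t = t, y = y, flags = flags, fitted = pred,
         spline = fit$spline, spar = fit$spar, edf = fit$edf,
         sigma = sigma, rmse = sqrt(mean(res^2)),
         ci_halfwidth = 1.96 * sigma),
    class = "gcc_spline"
  )
}

#' @export
print.gcc_spline <- function(x, ...) {
  cat("<gcc_spline> n = ", length(x$t), ", flagged = ", sum(x$flags),
      ", edf = ", round(x$edf, 2), ", rmse = ", signif(x$rmse, 4),
      ", ci halfwidth = ", signif(x$ci_halfwidth, 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted greenness spline
#'
#' @param object A `gcc_spline` from [detect_outliers()].
#' @param t Times at which to evaluate the smooth curve.
#' @param ... Unused.
#' @return Numeric vector of smoothed values.
#' @export
predict.gcc_spline <- function(object, t = object$t, ...) {
  stats::predict(object$spline, t)$y
}

#' Interpolation flag for long gaps
#'
#' Summary rows whose date lies strictly inside a gap of 14 days or more
#' between consecutive observed values are flagged 1, marking stretches
#' where the smoothed series is pure interpolation.
#'
#' @param dates Chronologically ordered window dates of the summary rows.
#' @param observed Logical, `TRUE` for rows with an observed (non-missing,
#'   unflagged) value.
#' @param gap_days Gap threshold in days (default 14; a 13-day gap is not
#'   flagged).
#' @return Integer vector of 0/1 flags, one per row.
#' @export
interpolation_flag <- function(dates, observed, gap_days = 14) {
  dates <- as.Date(dates)
  flag <- rep(0L, length(dates))
  obs_dates <- dates[observed]
  if (length(obs_dates) < 2) return(flag)
  for (i in seq_len(length(obs_dates) - 1)) {
    if (as.numeric(obs_dates[i + 1] - obs_dates[i]) >= gap_days) {
      inside <- dates > obs_dates[i] & dates < obs_dates[i + 1]
      flag[inside] <- 1L
    }
  }
  flag
}

#' Smooth a summary product and flag outliers
#'
#' Runs [detect_outliers()] independently on each of the eight Gcc/Rcc
#' summary statistics (`gcc_mean`, `gcc_50`, `gcc_75`, `gcc_90` and the
#' Rcc counterparts), fills the `smooth_*` columns with the final spline
#' evaluated at every window date (including windows with no data), sets
#' the `smooth_ci_*` columns to the 1.96-sigma confidence half-width, the
#' four `outlierflag_gcc_*` columns, and the `int_flag` column. Series
#' with fewer than 8 observations are left unsmoothed (`NA`).
#'
#' @param x A `pheno_summary` tibble.
#' @param cfg An [outlier_config()].
#' @param columns Series to smooth (default all eight).
#' @return `x` with smoothing columns populated and the per-series spline
#'   RMSE recorded in the `spline_rmse` attribute.
#' @export
smooth_summary <- function(x, cfg = outlier_config(),
                           columns = c(GCC_SERIES, RCC_SERIES)) {
  stopifnot(inherits(x, "pheno_summary"))
  t_all <- as.numeric(x$date - x$date[1])
  rmse <- stats::setNames(rep(NA_real_, 8), c(GCC_SERIES, RCC_SERIES))
  for (col in columns) {
    y <- x[[col]]
    obs <- !is.na(y)
    if (sum(obs) < 8) next
    fit <- detect_outliers(t_all[obs], y[obs], cfg)
    x[[paste0("smooth_", col)]] <- predict(fit, t_all)
    x[[paste0("smooth_ci_", col)]] <- fit$ci_halfwidth
    rmse[[col]] <- fit$rmse
    if (col %in% GCC_SERIES) {
      flags <- integer(nrow(x))
      flags[obs] <- fit$flags
      x[[paste0("outlierflag_", col)]] <- flags
    }
  }
  good <- !is.na(x$gcc_mean) & x$outlierflag_gcc_mean == 0L
  x$int_flag <- interpolation_flag(x$date, good)
  attr(x, "spline_rmse") <- rmse
  x
}
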