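#' Transition-date extraction configuration
#'
#' @param beta PELT penalty per changepoint, applied on the standardized
#'   (unit variance) scale of the smoothed series (default 0.5).
#' @param min_seg_days Minimum segment length in days (default 14;
#'   converted to `ceiling(14 / step)` samples for a given step).
#' @param thresholds Amplitude fractions at which transition dates are
#'   reported (default 10%, 25%, 50%).
#' @param z Normal quantile for the confidence band (default 1.96, a 95%
#'   interval).
#' @param min_amplitude Stages whose Gcc amplitude falls below
#'   `max(2 * spline RMSE, min_amplitude)` are discarded as noise
#'   (default 0.01 Gcc units, the conservative 99% confidence width of an
#'   individual Gcc value established by reference-panel analysis).
#' @return A `transition_config` list.
#' @export
transition_config <- function(beta = 0.5, min_seg_days = 14,
                              thresholds = c(0.10, 0.25, 0.50), z = 1.96,
                              min_amplitude = 0.01) {
  stopifnot(beta > 0, all(thresholds > 0 & thresholds < 1),
            !is.unsorted(thresholds))
  structure(list(beta = beta, min_seg_days = min_seg_days,
                 thresholds = thresholds, z = z,
                 min_amplitude = min_amplitude),
            class = "transition_config")
}

#' Changepoint detection by Pruned Exact Linear Time (PELT)
#'
#' Exact minimisation of the penalised segmentation objective
#' `sum of segment costs + beta * (number of changepoints)` under a
#' Gaussian change-in-mean cost (within-segment residual sum of squares),
#' subject to a minimum segment length. The pruning step discards
#' candidate changepoints that can never be optimal, so the result is
#' identical to the O(n^2) optimal-partitioning dynamic program.
#'
#' @param x Numeric signal (finite values).
#' @param beta Penalty per changepoint.
#' @param minseg Minimum segment length in samples (>= 2).
#' @return Sorted integer vector of changepoint positions: indices of the
#'   last sample of each segment except the final one (empty when no
#'   change is supported).
#' @export
pelt <- function(x, beta = 0.5, minseg = 2) {
  stopifnot(all(is.finite(x)), minseg >= 2)
  n <- length(x)
  if (n < 2 * minseg) return(integer(0))
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # RSS cost of segment (s+1)..t for 0-based boundaries s < t
  segcost <- function(s, t) {
    len <- t - s
    sx <- cs[t + 1] - cs[s + 1]
    (cs2[t + 1] - cs2[s + 1]) - sx^2 / len
  }
  f <- c(-beta, rep(Inf, n))  # f[tau + 1] = optimal cost of x[1..tau]
  last <- integer(n + 1)      # back-pointer: previous boundary
  cand <- 0L                  # candidate previous boundaries (0-based)
  # With a minimum segment length, a candidate failing the pruning test at
  # time t may still be needed at times t+1 .. t+minseg-1 (where t itself
  # is not yet an eligible boundary), so removal is delayed by minseg.
  expire <- rep(Inf, n + 1)
  for (t in seq_len(n)) {
    cand <- cand[expire[cand + 1] > t]
    el <- cand[t - cand >= minseg]
    if (length(el)) {
      cost <- segcost(el, t)
      vals <- f[el + 1] + cost + beta
      b <- which.min(vals)
      f[t + 1] <- vals[b]
      last[t + 1] <- el[b]
      mark <- el[f[el + 1] + cost > f[t + 1]]
      expire[mark + 1] <- pmin(expire[mark + 1], t + minseg)
    }
    cand <- c(cand, t)
  }
  if (!is.finite(f[n + 1])) return(integer(0))
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- last[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Segment a smoothed greenness series into rising and falling stages
#'
#' Changepoint segments are classified by the sign of the net smoothed
#' change; consecutive same-direction segments are merged (a changepoint
#' may split one long rise into pieces), stages whose amplitude falls
#' below the noise floor are discarded, and neighbours re-merged. Stages
#' may span calendar years, and a year may hold more than one
#' rising/falling cycle. For a rising stage the baseline `min_gcc` is the
#' smoothed minimum over the stage and `max_gcc` the smoothed maximum at
#' its peak; falling stages mirror this.
#'
#' @param dates Window dates of the smoothed series.
#' @param smooth Smoothed Gcc values (no missing values).
#' @param changepoints Changepoint indices from [pelt()].
#' @param rmse Spline residual RMSE, setting the noise floor
#'   `2 * rmse` for stage amplitudes.
#' @param cfg A [transition_config()].
#' @return A tibble of stages: `direction` (`"rising"`/`"falling"`),
#'   `start_idx`, `end_idx`, `start_date`, `end_date`, `min_gcc`,
#'   `max_gcc`, `amplitude`. Empty for flat (e.g. evergreen) series.
#' @export
extract_stages <- function(dates, smooth, changepoints, rmse,
                           cfg = transition_config()) {
  n <- length(smooth)
  bounds <- c(0L, changepoints, n)
  seg <- tibble::tibble(
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1]
  )
  seg$dir <- sign(smooth[seg$end] - smooth[seg$start])
  seg$dir[seg$dir == 0] <- 1  # degenerate flat segment; merge right
  # merge consecutive same-direction segments
  merge_runs <- function(seg) {
    seg$run <- cumsum(c(1L, diff(seg$dir) != 0))
    out <- dplyr::summarise(
      dplyr::group_by(seg, .data$run),
      start = min(.data$start), end = max(.data$end),
      dir = .data$dir[1], .groups = "drop")
    out[order(out$start), ]
  }
  seg <- merge_runs(seg)
  floor_amp <- max(2 * rmse, cfg$min_amplitude, na.rm = TRUE)
  repeat {
    amp <- vapply(seq_len(nrow(seg)), function(i) {
      v <- smooth[seg$start[i]:seg$end[i]]
      max(v) - min(v)
    }, numeric(1))
    drop <- which(amp < floor_amp)
    if (!length(drop) || nrow(seg) <= length(drop)) break
    seg <- seg[-drop[1], ]
    seg <- merge_runs(seg)
  }
  if (!nrow(seg)) return(empty_stages())
  amp <- vapply(seq_len(nrow(seg)), function(i) {
    v <- smooth[seg$start[i]:seg$end[i]]
    max(v) - min(v)
  }, numeric(1))
  keep <- amp >= floor_amp
  seg <- seg[keep, ]
  amp <- amp[keep]
  if (!nrow(seg)) return(empty_stages())
  # A changepoint can sit short of the actual smoothed extremum, so the
  # baseline minimum (preceding trough) and peak maximum are searched in
  # the stage plus its neighbouring stage on the relevant side.
  k <- nrow(seg)
  ext <- function(i, side) {
    j <- i + side
    if (j < 1 || j > k) seg$start[i]:seg$end[i]
    else min(seg$start[i], seg$start[j]):max(seg$end[i], seg$end[j])
  }
  min_gcc <- max_gcc <- numeric(k)
  for (i in seq_len(k)) {
    trough_side <- if (seg$dir[i] > 0) -1L else 1L
    min_gcc[i] <- min(smooth[ext(i, trough_side)])
    max_gcc[i] <- max(smooth[ext(i, -trough_side)])
  }
  tibble::tibble(
    direction = ifelse(seg$dir > 0, "rising", "falling"),
    start_idx = seg$start, end_idx = seg$end,
    start_date = dates[seg$start], end_date = dates[seg$end],
    min_gcc = min_gcc,
    max_gcc = max_gcc,
    amplitude = max_gcc - min_gcc
  )
}

empty_stages <- function() {
  tibble::tibble(direction = character(0), start_idx = integer(0),
                 end_idx = integer(0), start_date = as.Date(character(0)),
                 end_date = as.Date(character(0)), min_gcc = numeric(0),
                 max_gcc = numeric(0), amplitude = numeric(0))
}

# Transition and CI dates for one stage of one smoothed series.
# dates/smooth cover the whole series; ci is the constant band half-width;
# observed_dates are dates with an observed, unflagged value (used to widen
# the CI across missing-data runs).
stage_transition_dates <- function(stage, dates, smooth, ci, observed_dates,
                                   step, cfg = transition_config()) {
  idx <- stage$start_idx:stage$end_idx
  sm <- smooth[idx]
  d <- dates[idx]
  rising <- stage$direction == "rising"
  out <- list()
  for (f in cfg$thresholds) {
    thr <- stage$min_gcc + f * stage$amplitude
    pick <- function(values) {
      hit <- which(values >= thr)
      if (!length(hit)) return(NA_integer_)
      if (rising) hit[1] else hit[length(hit)]
    }
    i_tr <- pick(sm)
    if (is.na(i_tr)) {  # cannot happen for the threshold on sm itself
      i_tr <- if (rising) length(sm) else 1L
    }
    trans <- d[i_tr]
    i_hi <- pick(sm + ci)  # shifted-up curve crosses earlier
    i_lo <- pick(sm - ci)  # shifted-down curve crosses later
    clamp <- function(i, default) {
      if (is.na(i)) {
        warning("confidence band never crosses threshold within stage; ",
                "clamping to stage boundary", call. = FALSE)
        default
      } else i
    }
    if (rising) {
      lower <- d[clamp(i_hi, 1L)]
      upper <- d[clamp(i_lo, length(sm))]
    } else {
      lower <- d[clamp(i_lo, 1L)]
      upper <- d[clamp(i_hi, length(sm))]
    }
    # floor: at least one step either side, wider across missing data
    lower <- min(lower, trans - step)
    upper <- max(upper, trans + step)
    prev_obs <- observed_dates[observed_dates < trans]
    next_obs <- observed_dates[observed_dates > trans]
    if (length(prev_obs)) lower <- min(lower, max(prev_obs))
    if (length(next_obs)) upper <- max(upper, min(next_obs))
    pct <- sprintf("%d", round(100 * f))
    out[[paste0("transition_", pct)]] <- trans
    out[[paste0("transition_", pct, "_lower_ci")]] <- lower
    out[[paste0("transition_", pct, "_upper_ci")]] <- upper
    out[[paste0("threshold_", pct)]] <- thr
  }
  out
}

TRANSITION_COLS <- c(
  "sitename", "veg_type", "roi_id", "direction", "gcc_value",
  "transition_10", "transition_25", "transition_50",
  "transition_10_lower_ci", "transition_25_lower_ci",
  "transition_50_lower_ci",
  "transition_10_upper_ci", "transition_25_upper_ci",
  "transition_50_upper_ci",
  "threshold_10", "threshold_25", "threshold_50",
  "min_gcc", "max_gcc"
)

#' Extract phenophase transition dates from a smoothed summary product
#'
#' For each of the four Gcc statistics (`gcc_mean`, `gcc_50`, `gcc_75`,
#' `gcc_90`), the smoothed series is standardized and segmented with
#' [pelt()] into greenness rising and falling stages, and the dates at
#' which 10%, 25% and 50% of each stage's amplitude
#' (`max_gcc - min_gcc`) are reached are located on the smoothed curve at
#' the product's native date resolution. Confidence-interval dates come
#' from the crossings of the curve shifted by the 1.96-sigma band, with a
#' floor of one aggregation step (1 or 3 days) on either side, widened
#' across runs of missing data.
#'
#' @param x A smoothed `pheno_summary` (see [smooth_summary()]).
#' @param cfg A [transition_config()].
#' @return A `pheno_transitions` tibble, one row per stage and Gcc
#'   statistic, with the site identity, aggregation period and per-series
#'   spline RMSE carried in attributes.
#' @export
extract_transition_dates <- function(x, cfg = transition_config()) {
  stopifnot(inherits(x, "pheno_summary"))
  step <- attr(x, "step")
  minseg <- max(2L, as.integer(ceiling(cfg$min_seg_days / step)))
  rmse <- attr(x, "spline_rmse")
  if (is.null(rmse)) {
    # summary read back from file: recover the spline RMSE from the
    # residuals of the stored smooth about the unflagged observations
    rmse <- stats::setNames(vapply(GCC_SERIES, function(col) {
      keep <- !is.na(x[[col]]) & x[[paste0("outlierflag_", col)]] == 0L &
        !is.na(x[[paste0("smooth_", col)]])
      if (!any(keep)) return(NA_real_)
      sqrt(mean((x[[col]][keep] - x[[paste0("smooth_", col)]][keep])^2))
    }, numeric(1)), GCC_SERIES)
  }
  rows <- list()
  for (col in GCC_SERIES) {
    sm <- x[[paste0("smooth_", col)]]
    if (all(is.na(sm))) next
    ci <- x[[paste0("smooth_ci_", col)]][1]
    sd_sm <- stats::sd(sm)
    cps <- if (sd_sm > 0) {
      pelt((sm - mean(sm)) / sd_sm, beta = cfg$beta, minseg = minseg)
    } else integer(0)
    stages <- extract_stages(x$date, sm, cps, rmse[[col]], cfg)
    if (!nrow(stages)) next
    observed <- x$date[!is.na(x[[col]]) &
                         x[[paste0("outlierflag_", col)]] == 0L]
    for (i in seq_len(nrow(stages))) {
      td <- stage_transition_dates(stages[i, ], x$date, sm, ci, observed,
                                   step, cfg)
      rows[[length(rows) + 1]] <- tibble::as_tibble(c(
        list(sitename = attr(x, "sitename"), veg_type = attr(x, "veg_type"),
             roi_id = attr(x, "roi_id"),
             direction = stages$direction[i], gcc_value = col,
             min_gcc = stages$min_gcc[i], max_gcc = stages$max_gcc[i],
             start_date = stages$start_date[i]),
        td))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- dplyr::arrange(out, .data$start_date, .data$direction,
                          match(.data$gcc_value, GCC_SERIES))
    out$start_date <- NULL
    out <- out[TRANSITION_COLS]
  } else {
    out <- empty_transitions()
  }
  new_pheno_transitions(out, x, step, rmse)
}

empty_transitions <- function() {
  out <- tibble::tibble(
    sitename = character(0), veg_type = character(0), roi_id = character(0),
    direction = character(0), gcc_value = character(0))
  for (cn in grep("^transition", TRANSITION_COLS, value = TRUE)) {
    out[[cn]] <- as.Date(character(0))
  }
  for (cn in c("threshold_10", "threshold_25", "threshold_50",
               "min_gcc", "max_gcc")) {
    out[[cn]] <- numeric(0)
  }
  out[TRANSITION_COLS]
}

new_pheno_transitions <- function(x, meta_source, step, spline_rmse) {
  structure(
    tibble::as_tibble(x),
    sitename = attr(meta_source, "sitename"),
    veg_type = attr(meta_source, "veg_type"),
    roi_id = attr(meta_source, "roi_id"),
    step = step, spline_rmse = spline_rmse,
    class = c("pheno_transitions", class(tibble::tibble()))
  )
}

transitions_header <- function(x) {
  rmse <- attr(x, "spline_rmse")
  years <- if (nrow(x)) {
    range(as.integer(format(x$transition_50, "%Y")), na.rm = TRUE)
  } else c(NA_integer_, NA_integer_)
  rmse_line <- function(col) {
    v <- if (is.null(rmse) || is.na(rmse[[col]])) "NA"
      else fmt_num(rmse[[col]])
    sprintf("# Spline RMSE %s: %s", col, v)
  }
  c(
    "#",
    sprintf("# %d-day transition date estimates for %s_%s_%s",
            attr(x, "step"), attr(x, "sitename"), attr(x, "veg_type"),
            attr(x, "roi_id")),
    "#",
    sprintf("# Site: %s", attr(x, "sitename")),
    sprintf("# Veg Type: %s", attr(x, "veg_type")),
    sprintf("# ROI ID Number: %s", attr(x, "roi_id")),
    sprintf("# Aggregation Period: %d", attr(x, "step")),
    sprintf("# Year Min: %s", fmt_int(years[1])),
    sprintf("# Year Max: %s", fmt_int(years[2])),
    sprintf("# Creation Method: %s", TOOL_PROVENANCE),
    "# Update Method: recreated",
    rmse_line("gcc_mean"),
    rmse_line("gcc_50"),
    rmse_line("gcc_75"),
    rmse_line("gcc_90"),
    "#"
  )
}

#' Read / write a transition-date file
#'
#' The transition-date dialect has 16 `#` metadata lines (site identity,
#' aggregation period, year range, provenance, and per-statistic spline
#' RMSE), a column-header line, and one data row per stage and Gcc
#' statistic. Dates are ISO `YYYY-MM-DD`; data rows round-trip
#' byte-for-byte.
#'
#' @param path File path
#'   (`<sitename>_<veg_type>_<roi_id>_<step>day_transition_dates.csv`).
#' @return `read_transitions()` returns a `pheno_transitions` tibble;
#'   `write_transitions()` returns `path` invisibly.
#' @export
read_transitions <- function(path) {
  parts <- read_hash_csv(path)
  require_cols(parts$cols, TRANSITION_COLS, path)
  cells <- parts$cells
  colnames(cells) <- parts$cols
  date_cols <- grep("^transition", TRANSITION_COLS, value = TRUE)
  num_cols <- c("threshold_10", "threshold_25", "threshold_50",
                "min_gcc", "max_gcc")
  out <- tibble::tibble(
    sitename = cells[, "sitename"], veg_type = cells[, "veg_type"],
    roi_id = cells[, "roi_id"], direction = cells[, "direction"],
    gcc_value = cells[, "gcc_value"])
  if (!all(out$direction %in% c("rising", "falling"))) {
    stop("direction must be 'rising' or 'falling' in ", path, call. = FALSE)
  }
  for (cn in date_cols) {
    d <- na_date(cells[, cn])
    if (any(!is.na(cells[, cn]) & cells[, cn] != "NA" & is.na(d))) {
      stop("malformed date in column ", cn, " of ", path, call. = FALSE)
    }
    out[[cn]] <- d
  }
  for (cn in num_cols) out[[cn]] <- na_num(cells[, cn])
  out <- out[TRANSITION_COLS]
  h <- parts$header
  rmse <- stats::setNames(
    vapply(c("gcc_mean", "gcc_50", "gcc_75", "gcc_90"), function(col) {
      v <- hdr_value(h, paste0("Spline RMSE ", col))
      if (v %in% c("", "NA")) NA_real_ else as.numeric(v)
    }, numeric(1)),
    c("gcc_mean", "gcc_50", "gcc_75", "gcc_90"))
  meta <- structure(list(),
                    sitename = hdr_value(h, "Site"),
                    veg_type = hdr_value(h, "Veg Type"),
                    roi_id = hdr_value(h, "ROI ID Number"))
  new_pheno_transitions(out, meta,
                        as.integer(hdr_value(h, "Aggregation Period")),
                        rmse)
}

#' @rdname read_transitions
#' @param x A `pheno_transitions` tibble.
#' @export
write_transitions <- function(x, path) {
  stopifnot(inherits(x, "pheno_transitions"))
  date_cols <- grep("^transition", TRANSITION_COLS, value = TRUE)
  num_cols <- c("threshold_10", "threshold_25", "threshold_50",
                "min_gcc", "max_gcc")
  cols <- list(sitename = x$sitename, veg_type = x$veg_type,
               roi_id = x$roi_id, direction = x$direction,
               gcc_value = x$gcc_value)
  for (cn in date_cols) cols[[cn]] <- fmt_date(x[[cn]])
  for (cn in num_cols) cols[[cn]] <- fmt_num(x[[cn]])
  rows <- do.call(paste, c(cols[TRANSITION_COLS], sep = ","))
  writeLines(c(transitions_header(x),
               paste(TRANSITION_COLS, collapse = ","), rows), path)
  invisible(path)
}
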