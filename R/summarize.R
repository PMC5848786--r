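#' Quality-control configuration
#'
#' Images are excluded when the sun is less than `min_solar_elev` degrees
#' above the horizon, or when the ROI is too dark or too bright (mean
#' red + green + blue digital number below `dark_sum` or above
#' `bright_sum`). All three comparisons are strict, so boundary values
#' pass.
#'
#' @param min_solar_elev Minimum solar elevation in degrees (default 10).
#' @param dark_sum "Too dark" threshold on the ROI-mean DN sum
#'   (default 100).
#' @param bright_sum "Too bright" threshold on the ROI-mean DN sum
#'   (default 665).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_solar_elev = 10, dark_sum = 100, bright_sum = 665) {
  stopifnot(dark_sum < bright_sum)
  structure(list(min_solar_elev = min_solar_elev, dark_sum = dark_sum,
                 bright_sum = bright_sum), class = "qc_config")
}

#' Apply the image quality-control filters
#'
#' @param records A `roistats` tibble (or any data frame with
#'   `solar_elev`, `r_mean`, `g_mean`, `b_mean`).
#' @param cfg A [qc_config()].
#' @return The input with logical column `qc_pass` and character column
#'   `qc_reason` (`NA` for passing rows) appended.
#' @export
qc_pass <- function(records, cfg = qc_config()) {
  total <- records$r_mean + records$g_mean + records$b_mean
  reason <- dplyr::case_when(
    records$solar_elev < cfg$min_solar_elev ~ "low sun",
    total > cfg$bright_sum ~ "too bright",
    total < cfg$dark_sum ~ "too dark",
    .default = NA_character_
  )
  dplyr::mutate(records, qc_pass = is.na(reason), qc_reason = reason)
}

#' Aggregation windows for a calendar year
#'
#' At a 1-day step there is one window per calendar day. At a 3-day step
#' windows are centred on the fixed days-of-year 2, 5, 8, ..., 365 and
#' cover `{doy - 1, doy, doy + 1}`; the final window (labelled doy 365)
#' holds only days 364-365 in non-leap years and 364-366 in leap years,
#' keeping the doy grid identical across years.
#'
#' @param year Calendar year.
#' @param step Aggregation period in days, 1 or 3.
#' @return A tibble with columns `doy` (reported label), `date`
#'   (window-midpoint date) and `days` (list column of member doys).
#' @export
bin_windows <- function(year, step = 3) {
  stopifnot(step %in% c(1, 3))
  ndays <- if (is_leap_year(year)) 366L else 365L
  origin <- as.Date(sprintf("%d-01-01", year)) - 1
  if (step == 1) {
    doy <- seq_len(ndays)
    days <- as.list(doy)
  } else {
    doy <- seq(2L, 365L, by = 3L)
    days <- lapply(doy, function(d) {
      member <- (d - 1L):(d + 1L)
      member[member <= ndays]
    })
  }
  tibble::tibble(doy = as.integer(doy), date = origin + doy, days = days)
}

#' Select the midday image of a window
#'
#' Among the records dated on the window's middle day (for a 1-day window,
#' the day itself), returns the one whose time stamp is closest to
#' 12:00:00 local standard time; ties go to the earlier image. The midday
#' image is selected without quality-control filtering, so midday
#' statistics can be reported even when no image in the window passes QC.
#'
#' @param records All-image records (any QC status).
#' @param middle_date `Date` of the window's middle day.
#' @return A one-row tibble, or `NULL` when the middle day has no records.
#' @export
select_midday <- function(records, middle_date) {
  day <- records[records$date == as.Date(middle_date), , drop = FALSE]
  if (!nrow(day)) return(NULL)
  dist <- abs(hms_to_hours(day$local_std_time) - 12)
  day <- day[order(dist, day$local_std_time), , drop = FALSE]
  day[1, ]
}

SUMMARY_STAT_COLS <- c(
  "r_mean", "r_std", "g_mean", "g_std", "b_mean", "b_std",
  "gcc_mean", "gcc_std", "gcc_50", "gcc_75", "gcc_90",
  "rcc_mean", "rcc_std", "rcc_50", "rcc_75", "rcc_90"
)

GCC_SERIES <- c("gcc_mean", "gcc_50", "gcc_75", "gcc_90")
RCC_SERIES <- c("rcc_mean", "rcc_50", "rcc_75", "rcc_90")

SUMMARY_COLS <- c(
  "date", "year", "doy", "image_count", "midday_filename",
  "midday_r", "midday_g", "midday_b", "midday_gcc", "midday_rcc",
  SUMMARY_STAT_COLS, "max_solar_elev", "snowflag",
  paste0("outlierflag_", GCC_SERIES),
  paste0("smooth_", GCC_SERIES), paste0("smooth_", RCC_SERIES),
  paste0("smooth_ci_", GCC_SERIES), paste0("smooth_ci_", RCC_SERIES),
  "int_flag"
)

sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

qtl <- function(x, p) {
  if (!length(x)) return(NA_real_)
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

summarize_one_window <- function(valid, midday, snow_lookup) {
  row <- list(image_count = nrow(valid))
  if (!is.null(midday)) {
    row$midday_filename <- midday$filename
    row$midday_r <- midday$r_mean
    row$midday_g <- midday$g_mean
    row$midday_b <- midday$b_mean
    row$midday_gcc <- midday$gcc
    row$midday_rcc <- midday$rcc
    code <- snow_lookup[[midday$filename]]
    row$snowflag <- if (is.null(code)) NA_integer_ else as.integer(code)
  } else {
    row[c("midday_r", "midday_g", "midday_b", "midday_gcc",
          "midday_rcc")] <- NA_real_
    row$midday_filename <- NA_character_
    row$snowflag <- NA_integer_
  }
  if (nrow(valid)) {
    for (ch in c("r", "g", "b")) {
      v <- valid[[paste0(ch, "_mean")]]
      row[[paste0(ch, "_mean")]] <- mean(v)
      row[[paste0(ch, "_std")]] <- sd_or_na(v)
    }
    for (cc in c("gcc", "rcc")) {
      v <- valid[[cc]]
      row[[paste0(cc, "_mean")]] <- mean(v)
      row[[paste0(cc, "_std")]] <- sd_or_na(v)
      row[[paste0(cc, "_50")]] <- qtl(v, 0.50)
      row[[paste0(cc, "_75")]] <- qtl(v, 0.75)
      row[[paste0(cc, "_90")]] <- qtl(v, 0.90)
    }
    row$max_solar_elev <- max(valid$solar_elev)
  } else {
    row[SUMMARY_STAT_COLS] <- NA_real_
    row$max_solar_elev <- NA_real_
  }
  tibble::as_tibble(row)
}

#' Aggregate all-image records to a 1- or 3-day summary product
#'
#' Applies the quality-control filters, bins the passing records into
#' fixed day-of-year windows, selects the midday image of each window, and
#' computes midday and across-image aggregate statistics. Smoothed values,
#' outlier flags and the interpolation flag are then filled in by
#' [smooth_summary()] (called automatically by default).
#'
#' @param records A `roistats` tibble from [process_images()] or
#'   [read_roistats()].
#' @param step Aggregation period in days (1 or 3).
#' @param snow Optional snow-flag table: a data frame with columns
#'   `filename` and `code` (1-5), or a named vector keyed by midday image
#'   filename. Codes: 1 = bad/obscured image, 2 = no snow, 3 = snow
#'   (treeless sites), 4 = snow on ground only, 5 = snow on trees (and
#'   ground).
#' @param cfg A [qc_config()].
#' @param smooth If `TRUE` (default), run the spline smoothing and outlier
#'   detection and populate the `smooth_*`, `outlierflag_*` and `int_flag`
#'   columns.
#' @return A `pheno_summary` tibble, one row per window over all calendar
#'   years spanned by the records, with site/ROI metadata, step and QC
#'   thresholds carried in attributes.
#' @export
summarize_roistats <- function(records, step = 3, snow = NULL,
                               cfg = qc_config(), smooth = TRUE) {
  stopifnot(nrow(records) > 0)
  snow_lookup <- list()
  if (!is.null(snow)) {
    if (is.data.frame(snow)) {
      snow_lookup <- stats::setNames(as.list(snow$code), snow$filename)
    } else {
      snow_lookup <- as.list(snow)
    }
  }
  flagged <- qc_pass(records, cfg)
  years <- sort(unique(as.integer(format(records$date, "%Y"))))
  years <- seq(min(years), max(years))
  out <- purrr::map_dfr(years, function(yr) {
    win <- bin_windows(yr, step)
    origin <- as.Date(sprintf("%d-01-01", yr)) - 1
    purrr::map_dfr(seq_len(nrow(win)), function(i) {
      member_dates <- origin + win$days[[i]]
      in_win <- flagged[flagged$date %in% member_dates, , drop = FALSE]
      valid <- in_win[in_win$qc_pass, , drop = FALSE]
      midday <- select_midday(records, win$date[i])
      dplyr::bind_cols(
        tibble::tibble(date = win$date[i], year = as.integer(yr),
                       doy = win$doy[i]),
        summarize_one_window(valid, midday, snow_lookup))
    })
  })
  for (cn in c(paste0("outlierflag_", GCC_SERIES), "int_flag")) {
    out[[cn]] <- ifelse(is.na(out$gcc_mean) & cn != "int_flag",
                        NA_integer_, 0L)
  }
  for (cn in c(paste0("smooth_", c(GCC_SERIES, RCC_SERIES)),
               paste0("smooth_ci_", c(GCC_SERIES, RCC_SERIES)))) {
    out[[cn]] <- NA_real_
  }
  out <- out[SUMMARY_COLS]
  out <- new_pheno_summary(out, records, step, cfg)
  if (smooth) out <- smooth_summary(out) else out
}

#' Build a summary product from a plain greenness series
#'
#' Wraps an already-aggregated Gcc series (one value per window date, as
#' produced by [make_series()] or read from external sources) in the
#' summary-product container so it can flow through [smooth_summary()]
#' and [extract_transition_dates()]. All four Gcc statistics are set to
#' the series value, Rcc to `(1 - gcc) / 2`, and midday fields to `NA`.
#'
#' @param data Data frame with a `date` column and a Gcc column.
#' @param step Aggregation period of the series (1 or 3 days).
#' @param gcc Name of the Gcc column (default `"gcc"`).
#' @param sitename,veg_type,roi_id Identity recorded in the product.
#' @param smooth If `TRUE` (default), run [smooth_summary()].
#' @return A `pheno_summary` tibble.
#' @export
summary_from_series <- function(data, step, gcc = "gcc",
                                sitename = "series", veg_type = "XX",
                                roi_id = "0001", smooth = TRUE) {
  g <- data[[gcc]]
  date <- as.Date(data$date)
  out <- tibble::tibble(
    date = date,
    year = as.integer(format(date, "%Y")),
    doy = as.integer(strftime(date, "%j")),
    image_count = ifelse(is.na(g), 0L, 1L),
    midday_filename = NA_character_,
    midday_r = NA_real_, midday_g = NA_real_, midday_b = NA_real_,
    midday_gcc = g, midday_rcc = (1 - g) / 2)
  for (ch in c("r", "g", "b")) {
    out[[paste0(ch, "_mean")]] <- NA_real_
    out[[paste0(ch, "_std")]] <- NA_real_
  }
  for (cn in GCC_SERIES) out[[cn]] <- g
  out$gcc_std <- NA_real_
  for (cn in RCC_SERIES) out[[cn]] <- (1 - g) / 2
  out$rcc_std <- NA_real_
  out$max_solar_elev <- NA_real_
  out$snowflag <- NA_integer_
  for (cn in paste0("outlierflag_", GCC_SERIES)) {
    out[[cn]] <- ifelse(is.na(g), NA_integer_, 0L)
  }
  for (cn in c(paste0("smooth_", c(GCC_SERIES, RCC_SERIES)),
               paste0("smooth_ci_", c(GCC_SERIES, RCC_SERIES)))) {
    out[[cn]] <- NA_real_
  }
  out$int_flag <- 0L
  meta <- structure(list(), sitename = sitename, veg_type = veg_type,
                    roi_id = roi_id, lat = NA_real_, lon = NA_real_,
                    elevation = NA_real_, utc_offset = NA_real_)
  out <- new_pheno_summary(out[SUMMARY_COLS], meta, step, qc_config())
  if (smooth) smooth_summary(out) else out
}

new_pheno_summary <- function(x, meta_source, step, cfg,
                              spline_rmse = NULL) {
  structure(
    tibble::as_tibble(x),
    sitename = attr(meta_source, "sitename"),
    veg_type = attr(meta_source, "veg_type"),
    roi_id = attr(meta_source, "roi_id"),
    lat = attr(meta_source, "lat"), lon = attr(meta_source, "lon"),
    elevation = attr(meta_source, "elevation"),
    utc_offset = attr(meta_source, "utc_offset"),
    step = step, qc = cfg, spline_rmse = spline_rmse,
    class = c("pheno_summary", class(tibble::tibble()))
  )
}

summary_header <- function(x) {
  cfg <- attr(x, "qc")
  c(
    "#",
    sprintf("# %d-day summary product timeseries for %s_%s_%s",
            attr(x, "step"), attr(x, "sitename"), attr(x, "veg_type"),
            attr(x, "roi_id")),
    "#",
    sprintf("# Site: %s", attr(x, "sitename")),
    sprintf("# Veg Type: %s", attr(x, "veg_type")),
    sprintf("# ROI ID Number: %s", attr(x, "roi_id")),
    sprintf("# Lat: %s", fmt_num(attr(x, "lat"))),
    sprintf("# Lon: %s", fmt_num(attr(x, "lon"))),
    sprintf("# Elevation: %s", fmt_num(attr(x, "elevation"), 1)),
    sprintf("# UTC Offset: %s", fmt_num(attr(x, "utc_offset"), 1)),
    "# Image Count Threshold: 1",
    sprintf("# Aggregation Period: %d", attr(x, "step")),
    sprintf("# Solar Elevation Min: %s", fmt_num(cfg$min_solar_elev, 1)),
    "# Time of Day Min: 00:00:00",
    "# Time of Day Max: 23:59:59",
    sprintf("# ROI Brightness Min: %d", as.integer(cfg$dark_sum)),
    sprintf("# ROI Brightness Max: %d", as.integer(cfg$bright_sum)),
    sprintf("# Creation Method: %s", TOOL_PROVENANCE),
    "# Creation Parameters: defaults",
    "# Update Method: recreated",
    "# Smoothing: AICc-selected cubic smoothing spline",
    "# Outlier Rejection: Laplace, 4 SD above / 2 SD below, max 20 passes",
    "# Notes: missing values denoted NA",
    "#"
  )
}

#' Read / write a 1- or 3-day summary product file
#'
#' The summary dialect has 24 `#` metadata lines (site and ROI identity,
#' location, aggregation period, solar-elevation filter, dark/bright
#' brightness thresholds, provenance), a column-header line, and one data
#' row per window. Missing values are written `NA`; data rows round-trip
#' byte-for-byte.
#'
#' @param path File path (`<sitename>_<veg_type>_<roi_id>_<step>day.csv`).
#' @return `read_summary()` returns a `pheno_summary` tibble;
#'   `write_summary()` returns `path` invisibly.
#' @export
read_summary <- function(path) {
  parts <- read_hash_csv(path)
  require_cols(parts$cols, SUMMARY_COLS, path)
  cells <- parts$cells
  colnames(cells) <- parts$cols
  int_cols <- c("year", "doy", "image_count", "snowflag",
                paste0("outlierflag_", GCC_SERIES), "int_flag")
  chr_cols <- c("midday_filename")
  out <- tibble::tibble(date = na_date(cells[, "date"]))
  for (cn in setdiff(SUMMARY_COLS, "date")) {
    out[[cn]] <- if (cn %in% int_cols) na_int(cells[, cn])
      else if (cn %in% chr_cols) na_chr(cells[, cn])
      else na_num(cells[, cn])
  }
  h <- parts$header
  step <- as.integer(hdr_value(h, "Aggregation Period"))
  if (!step %in% c(1L, 3L)) {
    stop("bad or missing aggregation period in ", path, call. = FALSE)
  }
  cfg <- qc_config(
    min_solar_elev = hdr_num(h, "Solar Elevation Min"),
    dark_sum = hdr_num(h, "ROI Brightness Min"),
    bright_sum = hdr_num(h, "ROI Brightness Max"))
  meta <- structure(list(),
                    sitename = hdr_value(h, "Site"),
                    veg_type = hdr_value(h, "Veg Type"),
                    roi_id = hdr_value(h, "ROI ID Number"),
                    lat = hdr_num(h, "Lat"),
                    lon = hdr_num(h, "Lon"),
                    elevation = hdr_num(h, "Elevation"),
                    utc_offset = hdr_num(h, "UTC Offset"))
  new_pheno_summary(out, meta, step, cfg)
}

#' @rdname read_summary
#' @param x A `pheno_summary` tibble.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "pheno_summary"))
  int_cols <- c("year", "doy", "image_count", "snowflag",
                paste0("outlierflag_", GCC_SERIES), "int_flag")
  cols <- list(date = fmt_date(x$date),
               midday_filename = fmt_chr(x$midday_filename))
  for (cn in setdiff(SUMMARY_COLS, c("date", "midday_filename"))) {
    cols[[cn]] <- if (cn %in% int_cols) fmt_int(x[[cn]]) else fmt_num(x[[cn]])
  }
  rows <- do.call(paste, c(cols[SUMMARY_COLS], sep = ","))
  writeLines(c(summary_header(x),
               paste(SUMMARY_COLS, collapse = ","), rows), path)
  invisible(path)
}
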