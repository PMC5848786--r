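#' Chromatic coordinates from channel means
#'
#' The green chromatic coordinate Gcc = G / (R + G + B) and its red
#' analogue Rcc = R / (R + G + B), computed from the ROI-mean digital
#' number of each colour channel. Normalising by total brightness makes
#' the index invariant under multiplicative exposure changes, which is why
#' it suppresses most illumination variability. Achromatic scenes (snow,
#' leafless grey branches) sit near Gcc = 1/3.
#'
#' @param r_mean,g_mean,b_mean ROI-mean digital numbers (0-255) per
#'   channel; vectors recycle.
#' @return A tibble with columns `gcc` and `rcc`, `NA` where
#'   `r + g + b == 0`.
#' @examples
#' chromatic_coords(100, 100, 100)  # grey: gcc = 1/3
#' @export
chromatic_coords <- function(r_mean, g_mean, b_mean) {
  total <- r_mean + g_mean + b_mean
  gcc <- ifelse(total > 0, g_mean / total, NA_real_)
  rcc <- ifelse(total > 0, r_mean / total, NA_real_)
  tibble::tibble(gcc = gcc, rcc = rcc)
}

QTL_PROBS <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
QTL_SUFFIX <- c("5", "10", "25", "50", "75", "90", "95")

channel_stat_names <- function(ch) {
  c(paste0(ch, "_mean"), paste0(ch, "_std"),
    paste0(ch, "_", QTL_SUFFIX, "_qtl"))
}

ROISTATS_COLS <- c(
  "date", "local_std_time", "doy", "filename", "solar_elev", "exposure",
  "mask_index", "gcc", "rcc",
  channel_stat_names("r"), channel_stat_names("g"), channel_stat_names("b"),
  "r_g_cor", "g_b_cor", "b_r_cor"
)

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

safe_cor <- function(x, y) {
  if (pop_sd(x) == 0 || pop_sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-channel colour statistics over an ROI
#'
#' For each colour channel the mean, standard deviation (population
#' divisor, across all ROI pixels) and the 5th, 10th, 25th, 50th, 75th,
#' 90th and 95th percentiles of the digital-number distribution are
#' computed, together with the three pairwise Pearson correlations between
#' channels. Percentiles use linear interpolation between closest ranks.
#'
#' @param img Height x width x 3 digital-number array, already conformed to
#'   the mask dimensions.
#' @param mask An `roi_mask` logical matrix.
#' @return A one-row tibble with `gcc`, `rcc`, 9 statistics per channel and
#'   the 3 correlations (correlations are `NA` when a channel has zero
#'   variance).
#' @export
roi_channel_stats <- function(img, mask) {
  if (nrow(img) != nrow(mask) || ncol(img) != ncol(mask)) {
    stop("image and mask dimensions differ; conform_image() first",
         call. = FALSE)
  }
  px <- lapply(1:3, function(k) img[, , k][mask])
  names(px) <- c("r", "g", "b")
  stats <- lapply(px, function(v) {
    c(mean(v), pop_sd(v),
      stats::quantile(v, probs = QTL_PROBS, type = 7, names = FALSE))
  })
  out <- c(
    as.list(chromatic_coords(stats$r[1], stats$g[1], stats$b[1])),
    stats::setNames(as.list(stats$r), channel_stat_names("r")),
    stats::setNames(as.list(stats$g), channel_stat_names("g")),
    stats::setNames(as.list(stats$b), channel_stat_names("b")),
    list(r_g_cor = safe_cor(px$r, px$g),
         g_b_cor = safe_cor(px$g, px$b),
         b_r_cor = safe_cor(px$b, px$r))
  )
  tibble::as_tibble(out)
}

#' Process an image archive into the all-image product
#'
#' Runs the per-image stage of the pipeline: parse the filename timestamp,
#' compute solar elevation, select the ROI mask valid at that instant,
#' conform the image to the mask dimensions, and compute ROI colour
#' statistics and chromatic coordinates. Images whose timestamp falls
#' outside every mask window, and unreadable files, are skipped (with a
#' message), not emitted as rows.
#'
#' @param image_files Character vector of JPEG paths named
#'   `<sitename>_<YYYY_MM_DD>_<hhmmss>.jpg`.
#' @param roi An `roi_list`.
#' @param site Site metadata: a list (or `site_metadata`) with at least
#'   `lat`, `lon`, `elevation` and `utc_offset`.
#' @param mask_dir Directory containing the mask TIFF files named in the
#'   ROI list (default: directory of the first image).
#' @param exposure Optional named vector/list mapping image basenames to
#'   camera exposure values (pass-through; `NA` when absent).
#' @return A `roistats` tibble, chronologically sorted, one row per
#'   processed image, with site/ROI metadata in attributes.
#' @export
process_images <- function(image_files, roi, site,
                           mask_dir = dirname(image_files[1]),
                           exposure = NULL) {
  stopifnot(inherits(roi, "roi_list"), length(image_files) > 0)
  masks <- lapply(roi$entries$mask_file,
                  function(f) load_mask(file.path(mask_dir, f)))
  names(masks) <- roi$entries$mask_file
  resized <- FALSE
  rows <- vector("list", length(image_files))
  for (i in seq_along(image_files)) {
    f <- image_files[i]
    ts <- tryCatch(parse_image_filename(f), error = function(e) NULL)
    if (is.null(ts)) {
      message("skipping (bad filename): ", basename(f))
      next
    }
    entry <- select_mask(roi, ts$date, ts$local_std_time)
    if (is.null(entry)) next  # outside all mask windows
    img <- tryCatch(read_canopy_image(f), error = function(e) NULL)
    if (is.null(img)) {
      message("skipping (unreadable): ", basename(f))
      next
    }
    mask <- masks[[entry$mask_file]]
    if (nrow(img) != nrow(mask) || ncol(img) != ncol(mask)) {
      img <- conform_image(img, mask)
      resized <- TRUE
    }
    stats <- roi_channel_stats(img, mask)
    expo <- if (!is.null(exposure)) {
      v <- exposure[[basename(f)]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    } else NA_real_
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        date = ts$date, local_std_time = ts$local_std_time, doy = ts$doy,
        filename = basename(f),
        solar_elev = solar_elevation(ts$date, ts$local_std_time,
                                     site$lat, site$lon, site$utc_offset),
        exposure = expo, mask_index = entry$mask_index),
      stats)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$date, .data$local_std_time)
  out <- out[ROISTATS_COLS]
  new_roistats(out, sitename = roi$sitename, veg_type = roi$veg_type,
               roi_id = roi$roi_id, lat = site$lat, lon = site$lon,
               elevation = site$elevation, utc_offset = site$utc_offset,
               resized = resized)
}

new_roistats <- function(x, sitename, veg_type, roi_id, lat, lon, elevation,
                         utc_offset, resized = FALSE) {
  structure(
    tibble::as_tibble(x),
    sitename = sitename, veg_type = veg_type, roi_id = roi_id,
    lat = lat, lon = lon, elevation = elevation, utc_offset = utc_offset,
    resized = resized,
    class = c("roistats", class(tibble::tibble()))
  )
}

roistats_header <- function(x) {
  c(
    "#",
    sprintf("# ROI color statistics timeseries for %s_%s_%s",
            attr(x, "sitename"), attr(x, "veg_type"), attr(x, "roi_id")),
    "#",
    sprintf("# Site: %s", attr(x, "sitename")),
    sprintf("# Veg Type: %s", attr(x, "veg_type")),
    sprintf("# ROI ID Number: %s", attr(x, "roi_id")),
    sprintf("# Lat: %s", fmt_num(attr(x, "lat"))),
    sprintf("# Lon: %s", fmt_num(attr(x, "lon"))),
    sprintf("# Elevation: %s", fmt_num(attr(x, "elevation"), 1)),
    sprintf("# UTC Offset: %s", fmt_num(attr(x, "utc_offset"), 1)),
    sprintf("# Resized Images: %s",
            if (isTRUE(attr(x, "resized"))) "true" else "false"),
    sprintf("# Creation Method: %s", TOOL_PROVENANCE),
    "# Creation Parameters: defaults",
    "# Update Method: recreated",
    "# Notes: one data row per archived image",
    "#"
  )
}

#' Read / write an all-image colour statistics file
#'
#' The all-image dialect has 16 `#` metadata lines (site, vegetation type,
#' ROI id, location, UTC offset, resize flag, provenance), a column-header
#' line, and one comma-separated data row per image. Missing values are
#' written `NA`. Data rows round-trip byte-for-byte.
#'
#' @param path File path (`<sitename>_<veg_type>_<roi_id>_roistats.csv`).
#' @return `read_roistats()` returns a `roistats` tibble;
#'   `write_roistats()` returns `path` invisibly.
#' @export
read_roistats <- function(path) {
  parts <- read_hash_csv(path)
  require_cols(parts$cols, ROISTATS_COLS, path)
  cells <- parts$cells
  colnames(cells) <- parts$cols
  num_cols <- setdiff(ROISTATS_COLS,
                      c("date", "local_std_time", "doy", "filename",
                        "exposure", "mask_index"))
  out <- tibble::tibble(
    date = na_date(cells[, "date"]),
    local_std_time = cells[, "local_std_time"],
    doy = na_int(cells[, "doy"]),
    filename = cells[, "filename"]
  )
  out$solar_elev <- NULL
  for (cn in num_cols) out[[cn]] <- na_num(cells[, cn])
  out$exposure <- na_num(cells[, "exposure"])
  out$mask_index <- na_int(cells[, "mask_index"])
  out <- out[ROISTATS_COLS]
  h <- parts$header
  new_roistats(out,
               sitename = hdr_value(h, "Site"),
               veg_type = hdr_value(h, "Veg Type"),
               roi_id = hdr_value(h, "ROI ID Number"),
               lat = hdr_num(h, "Lat"),
               lon = hdr_num(h, "Lon"),
               elevation = hdr_num(h, "Elevation"),
               utc_offset = hdr_num(h, "UTC Offset"),
               resized = identical(hdr_value(h, "Resized Images"), "true"))
}

#' @rdname read_roistats
#' @param x A `roistats` tibble as returned by [process_images()].
#' @export
write_roistats <- function(x, path) {
  stopifnot(inherits(x, "roistats"))
  num_cols <- setdiff(ROISTATS_COLS,
                      c("date", "local_std_time", "doy", "filename",
                        "exposure", "mask_index"))
  cols <- list(
    date = fmt_date(x$date),
    local_std_time = x$local_std_time,
    doy = fmt_int(x$doy),
    filename = x$filename,
    exposure = fmt_int(x$exposure),
    mask_index = fmt_int(x$mask_index)
  )
  for (cn in num_cols) cols[[cn]] <- fmt_num(x[[cn]])
  rows <- do.call(paste, c(cols[ROISTATS_COLS], sep = ","))
  writeLines(c(roistats_header(x),
               paste(ROISTATS_COLS, collapse = ","), rows), path)
  invisible(path)
}
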