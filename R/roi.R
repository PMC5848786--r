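#' @title ROI lists, binary masks and field-of-view composites
#' @description A region of interest (ROI) delineates the vegetation within
#'   the camera field of view over which colour statistics are computed. An
#'   ROI is described by a *mask sequence*: one or more binary TIFF masks,
#'   each valid over a date/time window recorded in an ROI list file. New
#'   masks are appended when the camera field of view shifts.
#' @name roi-masks
NULL

VEG_TYPES <- c("AG", "DB", "DN", "EB", "EN", "GR", "MX", "SH", "TN", "WT",
               "NV", "RF", "XX")

ROI_COLS <- c("start_date", "start_time", "end_date", "end_time",
              "mask_file", "sample_image")

#' Construct an ROI list
#'
#' @param sitename Site name.
#' @param veg_type Two-letter vegetation type code (e.g. `"DB"` for
#'   deciduous broadleaf).
#' @param roi_id Four-digit ROI identifier (`"0001"` for the first ROI list
#'   of a vegetation type at a site).
#' @param entries Tibble with columns `start_date`, `start_time`,
#'   `end_date`, `end_time` (dates as `Date`, times as `"hh:mm:ss"`),
#'   `mask_file` and `sample_image`. The end date `9999-12-31` keeps a mask
#'   window open-ended.
#' @param description Free-text description of the vegetation delineated.
#' @return An object of class `roi_list`.
#' @export
roi_list <- function(sitename, veg_type, roi_id, entries, description = "") {
  veg_type <- toupper(veg_type)
  if (!veg_type %in% VEG_TYPES) {
    stop("unknown veg_type: ", veg_type, call. = FALSE)
  }
  entries <- tibble::as_tibble(entries)
  require_cols(names(entries), ROI_COLS, "roi entries")
  entries$start_date <- as.Date(entries$start_date)
  entries$end_date <- as.Date(entries$end_date)
  bad <- entries$start_date > entries$end_date |
    (entries$start_date == entries$end_date &
       entries$start_time > entries$end_time)
  if (any(bad)) {
    stop("ROI mask entry with start after end", call. = FALSE)
  }
  if (is.unsorted(entries$start_date)) {
    stop("ROI mask entries must be in chronological order", call. = FALSE)
  }
  entries$mask_index <- seq_len(nrow(entries))
  structure(
    list(sitename = sitename, veg_type = veg_type,
         roi_id = sprintf("%04d", as.integer(roi_id)),
         description = description,
         entries = entries[c(ROI_COLS, "mask_index")]),
    class = "roi_list"
  )
}

#' @export
print.roi_list <- function(x, ...) {
  cat("<roi_list> ", x$sitename, "_", x$veg_type, "_", x$roi_id,
      ": ", nrow(x$entries), " mask entr",
      if (nrow(x$entries) == 1) "y" else "ies", "\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Read / write an ROI list file
#'
#' The ROI list file dialect has 13 `#`-prefixed header lines documenting
#' provenance and the vegetation description, a column-header line
#' (`start_date,start_time,end_date,end_time,mask_file,sample_image`), and
#' one data row per mask entry. Data rows round-trip byte-for-byte.
#'
#' @param path File path (`<sitename>_<veg_type>_<roi_id>_roi.csv`).
#' @return `read_roi_list()` returns an `roi_list`; `write_roi_list()`
#'   returns `path` invisibly.
#' @export
read_roi_list <- function(path) {
  parts <- read_hash_csv(path)
  require_cols(parts$cols, ROI_COLS, path)
  cells <- parts$cells
  colnames(cells) <- parts$cols
  entries <- tibble::tibble(
    start_date = as.Date(cells[, "start_date"]),
    start_time = cells[, "start_time"],
    end_date = as.Date(cells[, "end_date"]),
    end_time = cells[, "end_time"],
    mask_file = cells[, "mask_file"],
    sample_image = cells[, "sample_image"]
  )
  site <- hdr_value(parts$header, "Site")
  veg <- hdr_value(parts$header, "Veg Type")
  id <- hdr_value(parts$header, "ROI ID Number")
  if (site == "" || veg == "" || id == "") {
    # fall back on the conventional filename
    nm <- strsplit(sub("_roi\\.csv$", "", basename(path)), "_")[[1]]
    if (length(nm) >= 3) {
      id <- nm[length(nm)]
      veg <- nm[length(nm) - 1]
      site <- paste(nm[seq_len(length(nm) - 2)], collapse = "_")
    }
  }
  roi_list(site, veg, id, entries,
           description = hdr_value(parts$header, "Description"))
}

#' @rdname read_roi_list
#' @param roi An `roi_list`.
#' @export
write_roi_list <- function(roi, path) {
  stopifnot(inherits(roi, "roi_list"))
  header <- c(
    "#",
    sprintf("# ROI List for %s", roi$sitename),
    "#",
    sprintf("# Site: %s", roi$sitename),
    sprintf("# Veg Type: %s", roi$veg_type),
    sprintf("# ROI ID Number: %s", roi$roi_id),
    sprintf("# Description: %s", roi$description),
    sprintf("# Creation Method: %s", TOOL_PROVENANCE),
    "# Maintainer:",
    "# Update Method: recreated",
    "# Notes:",
    "# Units: dates YYYY-MM-DD, times hh:mm:ss local standard",
    "#"
  )
  rows <- with(roi$entries, paste(
    fmt_date(start_date), start_time, fmt_date(end_date), end_time,
    mask_file, sample_image, sep = ","))
  writeLines(c(header, paste(ROI_COLS, collapse = ","), rows), path)
  invisible(path)
}

#' Load a binary ROI mask
#'
#' Masks are single-band 8-bit TIFF images, black (0) for pixels inside the
#' ROI and white (255) for pixels to exclude. Any value below digital
#' number 128 is treated as included; mid-grey and brighter is excluded.
#'
#' @param path Path to the TIFF mask file.
#' @return A logical matrix of class `roi_mask` (`TRUE` = pixel inside the
#'   ROI) with attribute `n_include`.
#' @export
load_mask <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (!is.null(bits) && !identical(as.integer(bits), 8L)) {
    stop("mask must be an 8-bit TIFF: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1) {
      stop("mask must be single-band: ", path, call. = FALSE)
    }
    img <- img[, , 1]
  }
  include <- round(img * 255) < 128
  if (!any(include)) {
    stop("empty ROI: no included pixels in mask ", path, call. = FALSE)
  }
  structure(include, class = c("roi_mask", "matrix", "array"),
            n_include = sum(include))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", nrow(x), "x", ncol(x), " pixels, ",
      attr(x, "n_include"), " included\n", sep = "")
  invisible(x)
}

#' Select the mask valid at a timestamp
#'
#' Returns the first mask entry whose date/time window (inclusive at both
#' ends) contains the given instant. Images outside every window are not
#' processed. Overlapping windows trigger a configuration warning; the
#' first match wins.
#'
#' @param roi An `roi_list`.
#' @param date `Date` of the image.
#' @param local_std_time `"hh:mm:ss"` local standard time.
#' @return A one-row tibble (the matching entry, with `mask_index`), or
#'   `NULL` when no window contains the timestamp.
#' @export
select_mask <- function(roi, date, local_std_time) {
  stopifnot(inherits(roi, "roi_list"))
  date <- as.Date(date)
  e <- roi$entries
  key <- paste(format(date, "%Y-%m-%d"), local_std_time)
  lo <- paste(format(e$start_date, "%Y-%m-%d"), e$start_time)
  hi <- paste(format(e$end_date, "%Y-%m-%d"), e$end_time)
  hit <- which(key >= lo & key <= hi)
  if (length(hit) > 1) {
    warning("overlapping ROI mask windows; first match wins", call. = FALSE)
  }
  if (!length(hit)) return(NULL)
  e[hit[1], ]
}

#' Read an RGB image as digital numbers
#'
#' @param path Path to a JPEG image.
#' @return A height x width x 3 array of digital numbers (0-255).
#' @export
read_canopy_image <- function(path) {
  img <- jpeg::readJPEG(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    stop("image is not RGB: ", path, call. = FALSE)
  }
  img[, , 1:3] * 255
}

# Separable bilinear resampling of one channel (matrix) to nrow_out x
# ncol_out, sampling at output pixel centres.
resize_channel <- function(m, nrow_out, ncol_out) {
  interp_weights <- function(n_in, n_out) {
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - if (n_in > 1) 1 else 0)
    frac <- pos - lo
    w <- matrix(0, n_out, n_in)
    w[cbind(seq_len(n_out), lo)] <- 1 - frac
    if (n_in > 1) w[cbind(seq_len(n_out), lo + 1)] <-
        w[cbind(seq_len(n_out), lo + 1)] + frac
    w
  }
  wr <- interp_weights(nrow(m), nrow_out)
  wc <- interp_weights(ncol(m), ncol_out)
  wr %*% m %*% t(wc)
}

#' Conform an image to the dimensions of a mask
#'
#' Some cameras change image resolution over time while the field of view
#' stays fixed; resizing on the fly lets a single mask apply throughout.
#' Bilinear interpolation is used so colour statistics stay smooth.
#'
#' @param img Height x width x 3 digital-number array.
#' @param mask An `roi_mask` (or any matrix) giving the target dimensions.
#' @return The image, resized to the mask dimensions if they differ.
#' @export
conform_image <- function(img, mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (nrow(img) == h && ncol(img) == w) return(img)
  if (abs(nrow(img) / ncol(img) - h / w) / (h / w) > 0.01) {
    warning("aspect ratio differs by more than 1%; resizing anyway",
            call. = FALSE)
  }
  out <- array(0, dim = c(h, w, 3))
  for (k in 1:3) out[, , k] <- resize_channel(img[, , k], h, w)
  out
}

#' Build a field-of-view shift composite image
#'
#' For each day of the year the centre column of pixels from that day's
#' midday image becomes one column of the composite; a shift in the
#' camera's field of view shows up as a vertical discontinuity. The
#' composite is an inspection aid for deciding where new ROI masks are
#' needed; shifts are not detected or corrected automatically.
#'
#' @param image_files Character vector of image file paths following the
#'   `<sitename>_<YYYY_MM_DD>_<hhmmss>.jpg` convention. For each calendar
#'   day the image closest to 12:00 local standard time is used.
#' @param year Calendar year of the composite.
#' @param fill Digital number (0-255) used for days with no image.
#' @param path Optional output path; when given the composite is written as
#'   a PNG.
#' @return Invisibly, the composite array (height x days-in-year x 3, DN).
#' @export
build_composite <- function(image_files, year, fill = 128, path = NULL) {
  if (!length(image_files)) stop("no images supplied", call. = FALSE)
  ts <- parse_image_filename(image_files)
  ts$file <- image_files
  ts <- ts[as.integer(format(ts$date, "%Y")) == year, ]
  if (!nrow(ts)) stop("no images in year ", year, call. = FALSE)
  ndays <- if (is_leap_year(year)) 366L else 365L
  midday <- ts |>
    dplyr::mutate(noon_dist = abs(hms_to_hours(.data$local_std_time) - 12)) |>
    dplyr::group_by(.data$doy) |>
    dplyr::arrange(.data$noon_dist, .data$local_std_time,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  first <- read_canopy_image(midday$file[1])
  h <- nrow(first); w <- ncol(first)
  centre <- floor(w / 2) + 1L  # 0-based floor(w/2)
  comp <- array(fill, dim = c(h, ndays, 3))
  for (i in seq_len(nrow(midday))) {
    img <- read_canopy_image(midday$file[i])
    if (nrow(img) != h || ncol(img) != w) {
      img <- conform_image(img, matrix(0, h, w))
    }
    comp[, midday$doy[i], ] <- img[, centre, ]
  }
  if (!is.null(path)) png::writePNG(comp / 255, path)
  invisible(comp)
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}
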