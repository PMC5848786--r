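#' Site metadata
#'
#' Site metadata records describe a camera site: its name, location
#' (latitude, longitude, elevation), the offset of local standard time
#' from UTC, the site class, date range, camera description, vegetation
#' and climate classifications, and free-text fields. `sitename`, `lat`,
#' `lon` and `utc_offset` are required; any other key-value pairs are
#' preserved verbatim through reads and writes.
#'
#' @param sitename Site name used in all file naming.
#' @param lat,lon Camera location in decimal degrees (longitude negative
#'   west of the prime meridian).
#' @param utc_offset Hours between UTC and local standard time (e.g. -5
#'   for Eastern Standard Time).
#' @param elevation Ground elevation in m above sea level.
#' @param ... Further key-value fields (e.g. `long_name`, `site_type`,
#'   `date_start`, `date_end`, `primary_veg_type`, `camera_description`).
#' @return A `site_metadata` list.
#' @export
site_metadata <- function(sitename, lat, lon, utc_offset, elevation = NA,
                          ...) {
  meta <- c(list(sitename = sitename, lat = lat, lon = lon,
                 elevation = elevation, utc_offset = utc_offset),
            list(...))
  validate_site_metadata(meta)
  structure(meta, class = "site_metadata")
}

validate_site_metadata <- function(meta) {
  for (key in c("sitename", "lat", "lon", "utc_offset")) {
    if (is.null(meta[[key]]) ||
        (is.character(meta[[key]]) && meta[[key]] == "")) {
      stop("site metadata is missing required field: ", key, call. = FALSE)
    }
  }
  lat <- as.numeric(meta$lat); lon <- as.numeric(meta$lon)
  if (is.na(lat) || abs(lat) > 90) stop("invalid lat", call. = FALSE)
  if (is.na(lon) || abs(lon) > 180) stop("invalid lon", call. = FALSE)
  invisible(meta)
}

# "-5" may arrive with a typographic minus sign from hand-edited files
normalize_minus <- function(x) gsub("−", "-", x)

#' Read / write site metadata
#'
#' Metadata are stored both in machine-readable JSON and as plain text
#' with one `key: value` pair per line; the two dialects round-trip into
#' each other losslessly, unknown keys included.
#'
#' @param path File path; format inferred from the extension (`.json` or
#'   `.txt`) unless given.
#' @param format `"json"` or `"text"`.
#' @return `read_site_metadata()` returns a `site_metadata` list;
#'   `write_site_metadata()` returns `path` invisibly.
#' @export
read_site_metadata <- function(path, format = c("auto", "json", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path)) "json" else "text"
  }
  if (format == "json") {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    keys <- sub(":.*$", "", lines)
    vals <- trimws(sub("^[^:]*:", "", lines))
    meta <- stats::setNames(as.list(vals), trimws(keys))
    for (key in c("lat", "lon", "elevation", "utc_offset", "nimage")) {
      if (!is.null(meta[[key]])) {
        meta[[key]] <- as.numeric(normalize_minus(meta[[key]]))
      }
    }
  }
  validate_site_metadata(meta)
  structure(meta, class = "site_metadata")
}

#' @rdname read_site_metadata
#' @param meta A `site_metadata` list.
#' @export
write_site_metadata <- function(meta, path,
                                format = c("auto", "json", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path)) "json" else "text"
  }
  validate_site_metadata(meta)
  fields <- unclass(meta)
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    vals <- vapply(fields, function(v) {
      if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
      else as.character(v)
    }, character(1))
    writeLines(paste0(names(fields), ": ", vals), path)
  }
  invisible(path)
}

#' @export
print.site_metadata <- function(x, ...) {
  cat("<site_metadata> ", x$sitename, " (", x$lat, ", ", x$lon,
      "), UTC", sprintf("%+g", as.numeric(x$utc_offset)), "\n", sep = "")
  invisible(x)
}
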