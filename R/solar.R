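#' Parse canopy-camera image filenames
#'
#' Image filenames follow the convention
#' `<sitename>_<YYYY_MM_DD>_<hhmmss>.jpg`, with the date and time stamp given
#' in local standard time (daylight saving is never applied). The sitename is
#' everything before the first `_YYYY_MM_DD_hhmmss` suffix, so sitenames
#' containing digits are allowed.
#'
#' @param filename Character vector of image filenames (basename or full
#'   path; any directory component is dropped).
#' @return A tibble with one row per filename and columns `sitename`,
#'   `date` (`Date`), `local_std_time` (`"hh:mm:ss"` character), and `doy`
#'   (integer day of year, 1-based).
#' @examples
#' parse_image_filename("harvard_2014_06_01_120000.jpg")
#' @export
parse_image_filename <- function(filename) {
  base <- basename(filename)
  pat <- "^(.+)_([0-9]{4})_([0-9]{2})_([0-9]{2})_([0-9]{6})\\.jpg$"
  ok <- grepl(pat, base)
  if (any(!ok)) {
    stop("malformed image filename(s): ", paste(base[!ok], collapse = ", "),
         call. = FALSE)
  }
  m <- regmatches(base, regexec(pat, base))
  sitename <- vapply(m, `[[`, character(1), 2)
  y <- vapply(m, `[[`, character(1), 3)
  mo <- vapply(m, `[[`, character(1), 4)
  d <- vapply(m, `[[`, character(1), 5)
  hms <- vapply(m, `[[`, character(1), 6)
  date <- as.Date(paste(y, mo, d, sep = "-"), format = "%Y-%m-%d")
  if (anyNA(date)) {
    bad <- base[is.na(date)]
    stop("invalid calendar date in filename(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  hh <- as.integer(substr(hms, 1, 2))
  mm <- as.integer(substr(hms, 3, 4))
  ss <- as.integer(substr(hms, 5, 6))
  if (any(hh > 23 | mm > 59 | ss > 59)) {
    bad <- base[hh > 23 | mm > 59 | ss > 59]
    stop("invalid time-of-day in filename(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    sitename = sitename,
    date = date,
    local_std_time = sprintf("%02d:%02d:%02d", hh, mm, ss),
    doy = as.integer(strftime(date, "%j"))
  )
}

#' Format an image filename from its components
#'
#' Inverse of [parse_image_filename()]: `parse -> format -> parse`
#' round-trips exactly.
#'
#' @param sitename Site name.
#' @param date `Date` (or coercible).
#' @param local_std_time `"hh:mm:ss"` local standard time.
#' @return Character vector of filenames.
#' @export
format_image_filename <- function(sitename, date, local_std_time) {
  date <- as.Date(date)
  paste0(sitename, "_", format(date, "%Y_%m_%d"), "_",
         gsub(":", "", local_std_time), ".jpg")
}

hms_to_hours <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(v) {
    v <- as.numeric(v)
    v[1] + v[2] / 60 + if (length(v) > 2) v[3] / 3600 else 0
  }, numeric(1))
}

#' Solar elevation angle
#'
#' Computes the elevation of the sun above the horizon for a site location
#' and a local-standard-time instant, using the NOAA low-precision solar
#' ephemeris (solar declination, equation of time, and hour angle).
#' Atmospheric refraction is ignored: the quality-control threshold applied
#' downstream (10 degrees) is coarse, and this formulation is accurate to
#' well under half a degree.
#'
#' @param date `Date` (or coercible) of the observation, local calendar.
#' @param local_std_time `"hh:mm:ss"` local standard time (no DST).
#' @param lat Latitude in decimal degrees.
#' @param lon Longitude in decimal degrees (negative west of the prime
#'   meridian).
#' @param utc_offset Difference in hours between local standard time and UTC
#'   (e.g. -5 for Eastern Standard Time); UTC instant = local - utc_offset.
#' @return Numeric vector of solar elevation angles in degrees, in
#'   (-90, 90].
#' @examples
#' solar_elevation("2015-03-20", "12:00:00", lat = 0, lon = 0, utc_offset = 0)
#' @export
solar_elevation <- function(date, local_std_time, lat, lon, utc_offset) {
  date <- as.Date(date)
  hours_local <- hms_to_hours(local_std_time)
  deg2rad <- pi / 180
  # Julian day of the UTC instant (Date epoch 1970-01-01 is JD 2440587.5)
  jd <- as.numeric(date) + 2440587.5 + (hours_local - utc_offset) / 24
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sin(gmas * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * deg2rad) * 0.000289
  truelong <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  applong <- truelong - 0.00569 - 0.00478 * sin(omega * deg2rad)
  mobliq <- 23 + (26 + (21.448 -
    jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mobliq + 0.00256 * cos(omega * deg2rad)
  declin <- asin(sin(obliq * deg2rad) * sin(applong * deg2rad)) / deg2rad
  vary <- tan(obliq / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (vary * sin(2 * gmls * deg2rad) -
    2 * ecc * sin(gmas * deg2rad) +
    4 * ecc * vary * sin(gmas * deg2rad) * cos(2 * gmls * deg2rad) -
    0.5 * vary^2 * sin(4 * gmls * deg2rad) -
    1.25 * ecc^2 * sin(2 * gmas * deg2rad))
  tst <- (hours_local * 60 + eqtime + 4 * lon - 60 * utc_offset) %% 1440
  ha <- tst / 4 - 180
  ha <- ifelse(ha < -180, ha + 360, ha)
  coszen <- sin(lat * deg2rad) * sin(declin * deg2rad) +
    cos(lat * deg2rad) * cos(declin * deg2rad) * cos(ha * deg2rad)
  coszen <- pmin(1, pmax(-1, coszen))
  90 - acos(coszen) / deg2rad
}
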