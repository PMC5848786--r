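#' @title Synthetic sites with known ground truth
#' @description The generator emulates the structures the pipeline
#'   consumes — seasonal canopy colour trajectories, illumination noise,
#'   snow events, gross outliers, and field-of-view shifts — with the
#'   generating parameters recorded as ground truth, so every pipeline
#'   stage can be tested end-to-end without real imagery.
#' @name synthetic-sites
NULL

# run code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Laplace deviates with standard deviation `sd` (scale b = sd / sqrt(2))
rlaplace_sd <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  b <- sd / sqrt(2)
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

#' Specify a synthetic camera site
#'
#' The seasonal Gcc trajectory is a double-logistic pulse
#' `baseline + amplitude * (plogis(spring_rate * (t - spring_mid)) -
#' plogis(autumn_rate * (t - autumn_mid)))`, the standard phenology curve
#' form; a second pulse can be added for bimodal (e.g. double-cropped or
#' Mediterranean) sites. Observation noise is Laplace, matching the
#' heavy-tailed residual model used by the outlier filter.
#'
#' @param sitename Site name (used in filenames).
#' @param year Calendar year simulated.
#' @param step Days between images / series samples (1 or 3).
#' @param lat,lon,elevation,utc_offset Site location; defaults place the
#'   site in the temperate north-east (42.5 N, 72.2 W, UTC-5), where noon
#'   sun is above the 10-degree QC threshold year-round.
#' @param baseline Dormant-season Gcc (default 0.35, a typical deciduous
#'   winter value).
#' @param amplitude Seasonal Gcc amplitude (default 0.10, typical of
#'   deciduous broadleaf canopies).
#' @param spring_mid,autumn_mid Logistic midpoints in day of year
#'   (defaults 120 and 270).
#' @param spring_rate,autumn_rate Logistic rates per day (defaults 0.15
#'   and 0.10; spring green-up is faster than autumn green-down).
#' @param second_pulse Optional list with `amplitude`, `spring_mid`,
#'   `spring_rate`, `autumn_mid`, `autumn_rate` for a second cycle.
#' @param noise Standard deviation of the Laplace observation noise on
#'   Gcc (default 0 = noiseless).
#' @param illum_sd SD of log illumination: each image is scaled by a
#'   multiplicative exposure factor `exp(N(0, illum_sd))`, which Gcc is
#'   invariant to (default 0).
#' @param snow_days Integer days of year on which the canopy is
#'   snow-covered: Gcc is pulled to the achromatic value 1/3.
#' @param outlier_frac Fraction of samples replaced by gross negative
#'   outliers (default 0).
#' @param outlier_shift Size of the gross outlier depression in Gcc units
#'   (default 10 times `noise`).
#' @param fov_shift Optional `list(doy =, offset =)`: from day `doy` the
#'   scene background is translated `offset` pixels, and a second ROI
#'   mask entry starts.
#' @param width,height Image dimensions in pixels.
#' @param brightness Target ROI channel-mean DN sum (default 300, inside
#'   the 100-665 QC window).
#' @param veg_type,roi_id ROI identity used in file naming.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_site_spec` list.
#' @export
synthetic_site_spec <- function(sitename = "greendale", year = 2015,
                                step = 1,
                                lat = 42.5, lon = -72.2, elevation = 340,
                                utc_offset = -5,
                                baseline = 0.35, amplitude = 0.10,
                                spring_mid = 120, spring_rate = 0.15,
                                autumn_mid = 270, autumn_rate = 0.10,
                                second_pulse = NULL,
                                noise = 0, illum_sd = 0,
                                snow_days = integer(0),
                                outlier_frac = 0,
                                outlier_shift = 10 * noise,
                                fov_shift = NULL,
                                width = 64, height = 48,
                                brightness = 300,
                                veg_type = "DB", roi_id = "0001",
                                seed = 42) {
  stopifnot(amplitude > 0, spring_mid < autumn_mid, step %in% c(1, 3))
  if (!is.null(second_pulse)) {
    stopifnot(second_pulse$spring_mid < second_pulse$autumn_mid)
  }
  structure(
    list(sitename = sitename, year = year, step = step, lat = lat,
         lon = lon, elevation = elevation, utc_offset = utc_offset,
         baseline = baseline, amplitude = amplitude,
         spring_mid = spring_mid, spring_rate = spring_rate,
         autumn_mid = autumn_mid, autumn_rate = autumn_rate,
         second_pulse = second_pulse, noise = noise, illum_sd = illum_sd,
         snow_days = as.integer(snow_days), outlier_frac = outlier_frac,
         outlier_shift = outlier_shift, fov_shift = fov_shift,
         width = width, height = height, brightness = brightness,
         veg_type = veg_type, roi_id = roi_id, seed = seed),
    class = "synthetic_site_spec"
  )
}

spec_pulses <- function(spec) {
  pulses <- list(list(amplitude = spec$amplitude,
                      spring_mid = spec$spring_mid,
                      spring_rate = spec$spring_rate,
                      autumn_mid = spec$autumn_mid,
                      autumn_rate = spec$autumn_rate))
  if (!is.null(spec$second_pulse)) pulses <- c(pulses, list(spec$second_pulse))
  pulses
}

#' Noiseless Gcc trajectory of a synthetic site
#'
#' @param spec A [synthetic_site_spec()].
#' @param t Day of year (possibly fractional).
#' @return Gcc values of the generating trajectory.
#' @export
trajectory_gcc <- function(spec, t) {
  g <- rep(spec$baseline, length(t))
  for (p in spec_pulses(spec)) {
    g <- g + p$amplitude *
      (stats::plogis(p$spring_rate * (t - p$spring_mid)) -
         stats::plogis(p$autumn_rate * (t - p$autumn_mid)))
  }
  g
}

# Analytic transition truth for each pulse, from the noiseless trajectory:
# stage extrema located by optimisation, threshold crossings by bisection.
trajectory_truth <- function(spec) {
  ndays <- if (is_leap_year(spec$year)) 366L else 365L
  pulses <- spec_pulses(spec)
  mids <- vapply(pulses, function(p) (p$spring_mid + p$autumn_mid) / 2,
                 numeric(1))
  o <- order(mids)
  pulses <- pulses[o]
  bounds <- c(1, vapply(seq_len(length(pulses) - 1), function(i) {
    (pulses[[i]]$autumn_mid + pulses[[i + 1]]$spring_mid) / 2
  }, numeric(1)), ndays)
  f <- function(t) trajectory_gcc(spec, t)
  rows <- list()
  for (i in seq_along(pulses)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    pk <- stats::optimize(f, c(lo, hi), maximum = TRUE)
    t_peak <- pk$maximum
    for (dirn in c("rising", "falling")) {
      win <- if (dirn == "rising") c(lo, t_peak) else c(t_peak, hi)
      base <- stats::optimize(f, win)$objective
      t_base <- stats::optimize(f, win)$minimum
      amp <- pk$objective - base
      cross <- vapply(c(0.10, 0.25, 0.50), function(fr) {
        thr <- base + fr * amp
        iv <- if (dirn == "rising") c(t_base, t_peak) else c(t_peak, t_base)
        stats::uniroot(function(t) f(t) - thr, sort(iv),
                       tol = 1e-8)$root
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        pulse = i, direction = dirn,
        transition_10 = cross[1], transition_25 = cross[2],
        transition_50 = cross[3],
        min_gcc = base, max_gcc = pk$objective)
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic Gcc series with ground truth
#'
#' Samples the site's trajectory on the step grid (for a 3-day step, the
#' fixed window-label days 2, 5, ..., 365), adds Laplace noise, replaces
#' snow days with achromatic values around 1/3, and injects gross
#' negative outliers. The true transition dates are solved from the
#' noiseless trajectory by bisection.
#'
#' @param spec A [synthetic_site_spec()].
#' @return A list: `series`, a tibble with `date`, `doy`, `gcc`,
#'   `is_snow`, `is_outlier`; and `truth`, a list with the generating
#'   spec, the noiseless `trajectory` on the grid, the analytic
#'   `transitions` tibble (fractional day of year), and the injected
#'   outlier indices.
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_site_spec"))
  origin <- as.Date(sprintf("%d-01-01", spec$year)) - 1
  doy <- bin_windows(spec$year, spec$step)$doy
  traj <- trajectory_gcc(spec, doy)
  with_seed(spec$seed, {
    gcc <- traj + rlaplace_sd(length(doy), spec$noise)
    is_snow <- doy %in% spec$snow_days
    gcc[is_snow] <- 1 / 3 + rlaplace_sd(sum(is_snow), spec$noise)
    is_out <- rep(FALSE, length(doy))
    n_out <- round(spec$outlier_frac * length(doy))
    if (n_out > 0) {
      idx <- sample(which(!is_snow), n_out)
      gcc[idx] <- traj[idx] - spec$outlier_shift *
        stats::runif(n_out, 0.8, 1.2)
      is_out[idx] <- TRUE
    }
    list(
      series = tibble::tibble(date = origin + doy, doy = doy, gcc = gcc,
                              is_snow = is_snow, is_outlier = is_out),
      truth = list(spec = spec, trajectory = traj,
                   transitions = trajectory_truth(spec),
                   outlier_idx = which(is_out))
    )
  })
}

# solve (r, g, b) channel DN for a target gcc at a given brightness sum;
# rcc takes up half the remainder so the colour stays inside the gamut
gcc_to_rgb <- function(gcc, total) {
  rcc <- (1 - gcc) / 2
  rgb <- c(rcc, gcc, 1 - gcc - rcc) * total
  if (any(rgb < 0) || any(rgb > 255)) {
    stop("requested gcc/brightness not representable in 8-bit RGB",
         call. = FALSE)
  }
  rgb
}

synth_background <- function(height, width, shift = 0) {
  rows <- seq_len(max(1L, floor(height / 3)))
  cols <- seq_len(width)
  # brightness ramp across columns: any horizontal scene translation
  # changes the centre column, so field-of-view shifts are visible in the
  # composite
  ramp <- 30 + ((cols + shift - 1) %% width) * (180 / width)
  bg <- matrix(rep(ramp, each = length(rows)), nrow = length(rows))
  list(rows = rows, values = bg)
}

#' Render a synthetic site's image archive
#'
#' Writes one midday (12:00:00 local standard time) JPEG per step day,
#' with the ROI block coloured so its mean chromatic coordinates follow
#' the site trajectory, a striped "landscape" background for the
#' field-of-view composite, per-image multiplicative illumination
#' factors, binary TIFF ROI masks with their ROI list file, site metadata
#' in both JSON and text form, and a ground-truth JSON.
#'
#' @param spec A [synthetic_site_spec()].
#' @param dir Output directory (created if needed).
#' @return A list: `dir`, `image_files`, `roi` (the `roi_list`), `meta`
#'   (the `site_metadata`), `roi_path`, `meta_json`, `truth` (as
#'   [make_series()]), `truth_path`.
#' @export
make_site_images <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_site_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_series(spec)
  series <- gen$series
  h <- spec$height; w <- spec$width
  bg_rows <- seq_len(max(1L, floor(h / 3)))
  roi_rows <- setdiff(seq_len(h), c(bg_rows, max(bg_rows) + 1:2))
  mask <- matrix(1, h, w)  # white = excluded
  mask[roi_rows, ] <- 0    # black = ROI
  shift_doy <- if (!is.null(spec$fov_shift)) spec$fov_shift$doy else NA
  illum <- with_seed(spec$seed + 1,
                     exp(stats::rnorm(nrow(series), 0, spec$illum_sd)))
  files <- character(nrow(series))
  for (i in seq_len(nrow(series))) {
    img <- array(0, dim = c(h, w, 3))
    offset <- if (!is.na(shift_doy) && series$doy[i] >= shift_doy) {
      spec$fov_shift$offset
    } else 0
    bg <- synth_background(h, w, offset)
    for (k in 1:3) img[bg$rows, , k] <- bg$values
    band <- setdiff(seq_len(h), bg$rows)
    rgb <- gcc_to_rgb(series$gcc[i], spec$brightness)
    for (k in 1:3) img[band, , k] <- rgb[k]
    img <- pmin(pmax(img * illum[i], 0), 255)
    fn <- format_image_filename(spec$sitename, series$date[i], "12:00:00")
    files[i] <- file.path(dir, fn)
    jpeg::writeJPEG(img / 255, files[i], quality = 0.95)
  }
  # masks + ROI list (a second entry when the field of view shifts)
  tag <- paste(spec$sitename, spec$veg_type, spec$roi_id, sep = "_")
  n_entries <- if (!is.na(shift_doy)) 2L else 1L
  origin <- as.Date(sprintf("%d-01-01", spec$year)) - 1
  mask_files <- sprintf("%s_%02d.tif", tag, seq_len(n_entries))
  for (mf in mask_files) {
    invisible(tiff::writeTIFF(mask, file.path(dir, mf),
                              bits.per.sample = 8))
  }
  starts <- c(origin + 1, if (n_entries == 2) origin + shift_doy)
  ends <- c(if (n_entries == 2) origin + shift_doy - 1,
            as.Date("9999-12-31"))
  sample_imgs <- vapply(starts, function(s) {
    basename(files[which(series$date >= s)[1]])
  }, character(1))
  entries <- tibble::tibble(
    start_date = starts,
    start_time = "00:00:00",
    end_date = ends,
    end_time = "23:59:59",
    mask_file = mask_files,
    sample_image = sample_imgs)
  roi <- roi_list(spec$sitename, spec$veg_type, spec$roi_id, entries,
                  description = "synthetic canopy block")
  roi_path <- file.path(dir, paste0(tag, "_roi.csv"))
  write_roi_list(roi, roi_path)
  meta <- site_metadata(
    sitename = spec$sitename, lat = spec$lat, lon = spec$lon,
    utc_offset = spec$utc_offset, elevation = spec$elevation,
    long_name = "synthetic site (generated fixture)",
    site_type = "I", primary_veg_type = spec$veg_type,
    date_start = format(min(series$date)),
    date_end = format(max(series$date)),
    nimage = length(files), active = "False",
    camera_description = "synthetic renderer")
  meta_json <- file.path(dir, paste0(spec$sitename, "_meta.json"))
  write_site_metadata(meta, meta_json)
  write_site_metadata(meta, file.path(dir,
                                      paste0(spec$sitename, "_meta.txt")))
  truth_path <- file.path(dir, paste0(spec$sitename, "_truth.json"))
  jsonlite::write_json(
    list(spec = unclass(spec)[!vapply(unclass(spec), is.null,
                                      logical(1))],
         transitions = gen$truth$transitions,
         outlier_idx = gen$truth$outlier_idx),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(dir = dir, image_files = files, roi = roi, meta = meta,
       roi_path = roi_path, meta_json = meta_json, truth = gen$truth,
       truth_path = truth_path)
}
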