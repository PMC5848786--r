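make_entries <- function() {
  tibble::tibble(
    start_date = as.Date(c("2012-01-01", "2013-05-01")),
    start_time = "00:00:00",
    end_date = as.Date(c("2013-04-30", "9999-12-31")),
    end_time = "23:59:59",
    mask_file = c("coweeta_DB_0001_01.tif", "coweeta_DB_0001_02.tif"),
    sample_image = c("coweeta_2012_06_01_120000.jpg",
                     "coweeta_2013_06_01_120000.jpg"))
}

test_that("ROI lists validate their entries", {
  roi <- roi_list("coweeta", "DB", "0001", make_entries())
  expect_s3_class(roi, "roi_list")
  expect_equal(roi$entries$mask_index, 1:2)
  expect_error(roi_list("coweeta", "ZZ", "0001", make_entries()),
               "veg_type")
  bad <- make_entries()
  bad$end_date[1] <- as.Date("2011-01-01")
  expect_error(roi_list("coweeta", "DB", "0001", bad), "start after end")
})

test_that("ROI list files round-trip byte-for-byte", {
  roi <- roi_list("coweeta", "DB", "0001", make_entries(),
                  description = "deciduous broadleaf canopy")
  p1 <- tempfile(fileext = ".csv")
  write_roi_list(roi, p1)
  lines <- readLines(p1)
  expect_equal(sum(grepl("^#", lines)), 13)  # header block
  expect_match(lines[14], "^start_date,start_time,end_date")
  back <- read_roi_list(p1)
  expect_equal(nrow(back$entries), 2)
  expect_true(any(back$entries$end_date == as.Date("9999-12-31")))
  p2 <- tempfile(fileext = ".csv")
  write_roi_list(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})

test_that("missing columns are a format error", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("#", "start_date,start_time,end_date,end_time,mask_file",
               "2012-01-01,00:00:00,9999-12-31,23:59:59,m.tif"), p)
  expect_error(read_roi_list(p), "sample_image")
  unlink(p)
})

test_that("masks load with the black-is-included convention", {
  all_black <- write_test_mask(matrix(0, 10, 10))
  m <- load_mask(all_black)
  expect_equal(attr(m, "n_include"), 100)

  all_white <- write_test_mask(matrix(255, 10, 10))
  expect_error(load_mask(all_white), "empty ROI")

  checker <- write_test_mask(matrix(c(0, 255), 10, 10))
  expect_equal(attr(load_mask(checker), "n_include"), 50)

  # mid-grey is excluded, just-below-mid is included
  grey <- write_test_mask(matrix(c(127, 128), 10, 10))
  expect_equal(attr(load_mask(grey), "n_include"), 50)
})

test_that("mask selection respects inclusive windows and time order", {
  roi <- roi_list("coweeta", "DB", "0001", make_entries())
  expect_null(select_mask(roi, "2011-06-01", "12:00:00"))
  # inclusive start boundary
  hit <- select_mask(roi, "2012-01-01", "00:00:00")
  expect_equal(hit$mask_index, 1L)
  # second window
  expect_equal(select_mask(roi, "2014-01-01", "10:00:00")$mask_index, 2L)
  # piecewise constant in time within a window
  for (tm in c("00:00:00", "06:30:00", "23:59:59")) {
    expect_equal(select_mask(roi, "2012-07-01", tm)$mask_index, 1L)
  }
})

test_that("overlapping windows warn and resolve to the first match", {
  e <- make_entries()
  e$end_date[1] <- as.Date("2013-06-30")  # overlaps second window
  roi <- roi_list("coweeta", "DB", "0001", e)
  expect_warning(hit <- select_mask(roi, "2013-06-01", "12:00:00"),
                 "overlap")
  expect_equal(hit$mask_index, 1L)
})

test_that("images are conformed to mask dimensions bilinearly", {
  img <- array(runif(640 * 480 * 3, 0, 255), dim = c(480, 640, 3))
  mask <- matrix(TRUE, 480, 640)
  expect_identical(conform_image(img, mask), img)  # identity

  half <- conform_image(img, matrix(TRUE, 240, 320))
  expect_equal(dim(half), c(240, 320, 3))

  # uniform colour survives resizing exactly
  uni <- array(rep(c(10, 200, 60), each = 100 * 80),
               dim = c(100, 80, 3))
  out <- conform_image(uni, matrix(TRUE, 50, 40))
  expect_equal(as.vector(out[, , 1]), rep(10, 2000))
  expect_equal(as.vector(out[, , 2]), rep(200, 2000))

  expect_warning(conform_image(uni, matrix(TRUE, 50, 80)),
                 "aspect ratio")
})

test_that("composite columns come from each day's midday centre column", {
  dir <- tempfile()
  dir.create(dir)
  cols <- list(c(250, 5, 5), c(5, 250, 5), c(5, 5, 250))
  for (i in 1:3) {
    write_test_jpeg(dir, "rgbsite", as.Date("2015-01-01") + (i - 1),
                    "12:00:00", cols[[i]], h = 8, w = 9)
  }
  files <- list.files(dir, full.names = TRUE)
  comp <- build_composite(files, 2015)
  expect_equal(ncol(comp), 365)  # non-leap year
  for (i in 1:3) {
    expect_equal(which.max(comp[1, i, ]), which.max(cols[[i]]))
  }
  # missing days carry the fill colour
  expect_true(all(comp[, 100, ] == 128))

  # identical images all year -> identical columns
  dir2 <- tempfile()
  dir.create(dir2)
  for (d in c("2016-01-01", "2016-06-01", "2016-12-31")) {
    write_test_jpeg(dir2, "flat", as.Date(d), "11:00:00", c(90, 120, 60))
  }
  comp2 <- build_composite(list.files(dir2, full.names = TRUE), 2016)
  expect_equal(ncol(comp2), 366)  # leap year
  expect_equal(comp2[, 1, ], comp2[, 153, ])
  unlink(c(dir, dir2), recursive = TRUE)
})
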