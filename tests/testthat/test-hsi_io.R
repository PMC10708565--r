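# Cube I/O, reflectance calibration, ROI extraction, replicate averaging and
# spectra-table round trips.

test_that("reflectance calibration matches the white/dark formula", {
  cube <- hsi_cube(array(c(90, 10, 50), dim = c(1, 1, 3)), c(1, 2, 3))
  frames <- list(white = matrix(90, 1, 1), dark = matrix(10, 1, 1))
  refl <- calibrate_reflectance(cube, frames)
  expect_equal(as.vector(refl$data), c(100, 0, 50))
  expect_false(any(refl$invalid_mask))
})

test_that("calibration flags invalid pixels and refuses all-invalid frames", {
  cube <- hsi_cube(array(1, dim = c(2, 2, 2)), c(1, 2))
  white <- matrix(c(5, 5, 0, 5), 2, 2)  # pixel (1,2): white - dark = -1
  dark <- matrix(1, 2, 2)
  refl <- calibrate_reflectance(cube, list(white = white, dark = dark))
  expect_true(all(is.nan(refl$data[1, 2, ])))
  expect_true(all(refl$invalid_mask[1, 2, ]))
  expect_false(any(refl$invalid_mask[2, , ]))
  expect_error(
    calibrate_reflectance(cube, list(white = matrix(0, 2, 2), dark = dark)),
    "calibration error")
})

test_that("calibration is invariant to affine re-encoding of the counts", {
  set.seed(11)
  raw <- array(runif(4 * 5 * 3, 20, 80), dim = c(4, 5, 3))
  white <- matrix(runif(20, 90, 110), 4, 5)
  dark <- matrix(runif(20, 0, 10), 4, 5)
  r1 <- calibrate_reflectance(hsi_cube(raw, 1:3),
                              list(white = white, dark = dark))
  a <- 2.5; b <- -7
  r2 <- calibrate_reflectance(hsi_cube(a * raw + b, 1:3),
                              list(white = a * white + b,
                                   dark = a * dark + b))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("3-D frames take precedence over the 2-D interpretation", {
  cube <- hsi_cube(array(50, dim = c(2, 2, 2)), c(1, 2))
  white3 <- array(rep(c(100, 200), each = 4), dim = c(2, 2, 2))
  refl <- calibrate_reflectance(cube, list(white = white3,
                                           dark = matrix(0, 2, 2)))
  expect_equal(refl$data[1, 1, ], c(50, 25))
})

test_that("ROI mask erosion follows the margin and the brute-force oracle", {
  fg <- matrix(TRUE, 10, 10)
  expect_equal(build_roi_mask(fg, margin_mm = 0, px_per_mm = 1)$mask, fg)
  roi <- build_roi_mask(fg, margin_mm = 2, px_per_mm = 1)
  expect_equal(sum(roi$mask), 36)  # 6x6 interior block
  expect_true(all(which(roi$mask, arr.ind = TRUE) >= 3) &&
              all(which(roi$mask, arr.ind = TRUE) <= 8))
  expect_error(build_roi_mask(matrix(TRUE, 3, 3), 2, 1), "ROI error")

  set.seed(21)
  for (r in 0:3) {
    fg2 <- matrix(runif(15 * 12) > 0.25, 15, 12)
    if (!any(brute_erode(fg2, r))) next
    expect_equal(build_roi_mask(fg2, margin_mm = r, px_per_mm = 1)$mask,
                 brute_erode(fg2, r))
  }
})

test_that("erosion is monotone: larger margins never grow the ROI", {
  set.seed(5)
  fg <- matrix(runif(20 * 20) > 0.15, 20, 20)
  prev <- build_roi_mask(fg, 0, 1)$mask
  for (r in 1:3) {
    cur <- tryCatch(build_roi_mask(fg, r, 1)$mask,
                    error = function(e) matrix(FALSE, 20, 20))
    expect_true(all(!cur | prev))  # cur subset of prev
    prev <- cur
  }
})

test_that("roi_mean_spectrum matches an explicit pixel loop", {
  set.seed(31)
  d <- c(8, 8, 5)
  raw <- array(runif(prod(d), 10, 90), dim = d)
  white <- matrix(100, 8, 8); white[2, 3] <- 0  # invalid pixel
  refl <- calibrate_reflectance(hsi_cube(raw, 1:5),
                                list(white = white, dark = matrix(0, 8, 8)))
  mask <- matrix(runif(64) > 0.4, 8, 8)
  mask[2, 3] <- TRUE  # force the invalid pixel into the ROI
  got <- roi_mean_spectrum(refl, mask)
  want <- sapply(1:5, function(b) {
    acc <- c()
    for (i in 1:8) for (j in 1:8) {
      if (mask[i, j] && !refl$invalid_mask[i, j, b]) {
        acc <- c(acc, refl$data[i, j, b])
      }
    }
    mean(acc)
  })
  expect_equal(got, want, tolerance = 1e-12)

  # uniform cube and singleton ROI
  refl2 <- calibrate_reflectance(hsi_cube(array(50, dim = d), 1:5),
                                 list(white = matrix(100, 8, 8),
                                      dark = matrix(0, 8, 8)))
  expect_equal(roi_mean_spectrum(refl2, matrix(TRUE, 8, 8)), rep(50, 5))
  single <- matrix(FALSE, 8, 8); single[4, 4] <- TRUE
  expect_equal(roi_mean_spectrum(refl, single), refl$data[4, 4, ])
})

test_that("replicate averaging is the elementwise mean", {
  v <- c(1.5, 2.5)
  expect_equal(average_replicates(list(v, v, v)), v)
  expect_equal(average_replicates(list(c(0, 0), c(2, 4), c(4, 2))), c(2, 2))
  expect_equal(average_replicates(list(v)), v)
  expect_error(average_replicates(list(1:2, 1:3)), "dimension error")
})

test_that("spectra tables round-trip and enforce the format", {
  s <- spectra_set(matrix(c(pi, exp(1), sqrt(2), 1/3, 2/7, 1e-8), 2, 3),
                   c(900.5, 1000, 1100.25), c("a", "b"), "crushed")
  path <- tempfile(fileext = ".csv")
  write_spectra_table(s, path)
  s2 <- read_spectra_table(path, "crushed")
  expect_identical(s2$X, s$X)
  expect_identical(s2$sample_ids, s$sample_ids)
  expect_equal(s2$wavelengths, s$wavelengths)

  # unsorted wavelength columns are re-sorted ascending
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,1100,900,1000", "a,3,1,2", "b,6,4,5"), p2)
  expect_message(s3 <- read_spectra_table(p2), "re-sorted")
  expect_equal(s3$wavelengths, c(900, 1000, 1100))
  expect_equal(unname(s3$X[1, ]), c(1, 2, 3))

  p3 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,900,1000", "a,1,2", "a,3,4"), p3)
  expect_error(read_spectra_table(p3), "duplicate sample_id")

  p4 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,900,banana", "a,1,2"), p4)
  expect_error(read_spectra_table(p4), "non-numeric wavelength header")
})

test_that("ENVI cubes round-trip bit-identically in all interleaves", {
  set.seed(41)
  cube <- hsi_cube(array(rnorm(6 * 5 * 4), dim = c(6, 5, 4)),
                   c(900, 910.5, 921, 931.5))
  for (il in c("bsq", "bil", "bip")) {
    path <- tempfile(fileext = ".raw")
    write_cube(cube, path, "envi", interleave = il)
    back <- read_cube(path, "envi")
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
  }
})

test_that("a conformant 256-band ENVI file reads with its wavelength axis", {
  wl <- seq(885, 1735, length.out = 256)
  cube <- hsi_cube(array(runif(3 * 3 * 256), dim = c(3, 3, 256)), wl)
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path, "envi", interleave = "bil")
  back <- read_cube(paste0(path, ".hdr"), "envi")
  expect_length(back$wavelengths, 256)
  expect_equal(range(back$wavelengths), c(885, 1735))
})

test_that("ENVI header errors name the offending field", {
  path <- tempfile(fileext = ".raw")
  writeBin(rep(0, 8), path, size = 8)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 5", "interleave = bsq",
               "wavelength = {1, 2, 3}"), paste0(path, ".hdr"))
  expect_error(read_cube(path, "envi"), "wavelength")
  writeLines(c("ENVI", "samples = 2", "lines = 2",
               "data type = 5", "interleave = bsq",
               "wavelength = {1, 2}"), paste0(path, ".hdr"))
  expect_error(read_cube(path, "envi"), "bands")
})

test_that("flat-table cubes cover the minimal contract", {
  cube <- hsi_cube(array(c(0.1, 0.2, 0.3), dim = c(1, 1, 3)), c(1, 2, 3))
  path <- tempfile(fileext = ".txt")
  write_cube(cube, path, "flat_table")
  back <- read_cube(path, "flat_table")
  expect_identical(back$data, cube$data)
  expect_equal(back$wavelengths, c(1, 2, 3))
})
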