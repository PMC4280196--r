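test_that("ENVI round trip is lossless across interleaves and dtypes", {
  set.seed(11)
  wl <- seq(500, 900, length.out = 5)
  # float32-representable values so the size-4 round trip is exact too
  vals <- round(runif(8 * 6 * 5) * 256) / 256
  cube <- hypercube(array(vals, c(8, 6, 5)), wl)
  for (il in c("bil", "bsq", "bip")) {
    for (dt in c(5, 4)) {
      path <- file.path(tempdir(), sprintf("rt_%s_%d.img", il, dt))
      write_envi(cube, path, interleave = il, data_type = dt)
      back <- read_envi(path)
      expect_identical(back$data, cube$data, label = sprintf("%s dtype %d", il, dt))
      expect_equal(back$wavelengths, wl)
    }
  }
  # int16 path quantises: check with integer-valued cube
  icube <- hypercube(array(sample.int(1000, 8 * 6 * 5, TRUE), c(8, 6, 5)) * 1.0, wl)
  path <- file.path(tempdir(), "rt_int.img")
  write_envi(icube, path, interleave = "bil", data_type = 2)
  expect_identical(read_envi(path)$data, icube$data)
})

test_that("BSQ and BIL writes of the same cube read back equal", {
  set.seed(12)
  cube <- hypercube(array(rnorm(7 * 5 * 4), c(7, 5, 4)), c(400, 500, 600, 700))
  p1 <- file.path(tempdir(), "ilv1.img")
  p2 <- file.path(tempdir(), "ilv2.img")
  write_envi(cube, p1, interleave = "bsq")
  write_envi(cube, p2, interleave = "bil")
  expect_identical(read_envi(p1)$data, read_envi(p2)$data)
})

test_that("malformed ENVI input is rejected with a format error", {
  cube <- hypercube(array(1, c(3, 3, 2)), c(500, 600))
  path <- file.path(tempdir(), "bad.img")
  write_envi(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  # band count disagreeing with the wavelength list
  writeLines(sub("bands = 2", "bands = 3", hdr), paste0(path, ".hdr"))
  expect_error(read_envi(path), "wavelength|size")
  # missing mandatory field
  writeLines(hdr[!grepl("^samples", hdr)], paste0(path, ".hdr"))
  expect_error(read_envi(path), "missing field")
  # file size mismatch
  writeLines(sub("lines = 3", "lines = 4", hdr), paste0(path, ".hdr"))
  expect_error(read_envi(path), "size")
})

test_that("hypercube construction enforces its invariants", {
  expect_error(hypercube(matrix(1, 2, 2), 1:2), "3-D")
  expect_error(hypercube(array(1, c(2, 2, 3)), c(500, 600)), "bands")
  expect_error(hypercube(array(1, c(2, 2, 2)), c(600, 500)), "increasing")
})

test_that("calibration maps white to 1, dark to 0 and the midpoint to 0.5", {
  wl <- seq(400, 700, length.out = 4)
  set.seed(13)
  white <- hypercube(array(runif(5 * 4 * 4, 2000, 3000), c(5, 4, 4)), wl)
  dark <- hypercube(array(runif(5 * 4 * 4, 50, 150), c(5, 4, 4)), wl)
  expect_equal(calibrate(white, white, dark)$data, array(1, c(5, 4, 4)))
  expect_equal(calibrate(dark, white, dark)$data, array(0, c(5, 4, 4)))
  mid <- hypercube((white$data + dark$data) / 2, wl)
  expect_equal(calibrate(mid, white, dark)$data, array(0.5, c(5, 4, 4)))
  expect_true(calibrate(mid, white, dark)$reflectance)
})

test_that("zero-denominator pixels are flagged invalid and excluded from ROI means", {
  wl <- c(500, 600)
  white <- hypercube(array(100, c(2, 2, 2)), wl)
  dark_mat <- array(10, c(2, 2, 2))
  dark_mat[1, 1, ] <- 100  # dead pixel: white == dark
  dark <- hypercube(dark_mat, wl)
  raw <- hypercube(array(55, c(2, 2, 2)), wl)
  refl <- calibrate(raw, white, dark)
  expect_true(all(is.na(refl$data[1, 1, ])))
  mask <- matrix(TRUE, 2, 2)
  expect_equal(unname(mean_roi_spectrum(refl, mask)), c(0.5, 0.5))
})

test_that("ROI mean matches a brute-force per-band loop", {
  set.seed(14)
  cube <- hypercube(array(runif(6 * 5 * 7), c(6, 5, 7)), seq(420, 1000, length.out = 7))
  mask <- matrix(FALSE, 6, 5)
  mask[sample.int(30, 10)] <- TRUE
  got <- unname(mean_roi_spectrum(cube, mask))
  manual <- numeric(7)
  for (b in 1:7) {
    acc <- c()
    for (i in 1:6) for (j in 1:5) if (mask[i, j]) acc <- c(acc, cube$data[i, j, b])
    manual[b] <- mean(acc)
  }
  expect_equal(got, manual)
  # two-pixel ROI: (a + b) / 2
  m2 <- matrix(FALSE, 6, 5); m2[c(2, 9)] <- TRUE
  expect_equal(unname(mean_roi_spectrum(cube, m2)),
               (cube$data[2, 1, ] + cube$data[3, 2, ]) / 2)
  expect_error(mean_roi_spectrum(cube, matrix(FALSE, 6, 5)), "no TRUE pixel")
})

test_that("mean-then-calibrate equals per-pixel calibration averaged (loop oracle)", {
  set.seed(15)
  wl <- seq(500, 800, length.out = 4)
  raw <- hypercube(array(runif(5 * 5 * 4, 500, 2500), c(5, 5, 4)), wl)
  white <- hypercube(array(runif(5 * 5 * 4, 2600, 3000), c(5, 5, 4)), wl)
  dark <- hypercube(array(runif(5 * 5 * 4, 10, 90), c(5, 5, 4)), wl)
  mask <- matrix(runif(25) > 0.4, 5, 5)
  refl <- calibrate(raw, white, dark)
  got <- unname(mean_roi_spectrum(refl, mask))
  manual <- numeric(4)
  for (b in 1:4) {
    vals <- c()
    for (i in 1:5) for (j in 1:5) {
      if (mask[i, j]) {
        vals <- c(vals, (raw$data[i, j, b] - dark$data[i, j, b]) /
                    (white$data[i, j, b] - dark$data[i, j, b]))
      }
    }
    manual[b] <- mean(vals)
  }
  expect_equal(got, manual)
})

test_that("band trimming keeps the closed interval, preserves order and is idempotent", {
  cube <- hypercube(array(seq_len(2 * 2 * 3), c(2, 2, 3)), c(400, 500, 600))
  tr <- trim_bands(cube, 450, 650)
  expect_equal(tr$wavelengths, c(500, 600))
  expect_equal(tr$data, cube$data[, , 2:3])
  # closed interval: endpoints survive
  expect_equal(trim_bands(cube, 400, 600)$wavelengths, c(400, 500, 600))
  # identity on the full range, idempotent on repeat
  expect_equal(trim_bands(cube, 390, 610)$data, cube$data)
  tr2 <- trim_bands(tr, 450, 650)
  expect_equal(tr2$wavelengths, tr$wavelengths)
  expect_error(trim_bands(cube, 650, 700), "no band")
  expect_error(trim_bands(cube, 700, 650), "smaller")
  tab <- random_table(5, 6)
  expect_equal(trim_bands(tab, 420, 1000)$x, tab$x)
  expect_true(all(diff(trim_bands(tab, 500, 900)$wavelengths) > 0))
})

test_that("spectra tables round-trip through CSV exactly", {
  tab <- random_table(7, 5, seed = 3)
  path <- file.path(tempdir(), "spectra.csv")
  write_spectra_csv(tab, path)
  back <- read_spectra_csv(path)
  expect_equal(back$x, tab$x)
  expect_equal(back$y, tab$y)
  expect_equal(back$wavelengths, tab$wavelengths)
  expect_identical(back$organ, tab$organ)
})
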