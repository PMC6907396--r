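test_that("multipage TIFF volumes round-trip bit-exactly", {
  v <- fx_small_volume()
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  r <- read_volume(f, spacing_override = c(2, 1, 1))
  expect_identical(dim(r$data), dim(v$data))
  expect_true(all(r$data == v$data))
  expect_equal(vol_spacing(r), c(2, 1, 1))
})

test_that("slice directories stack in natural-number order", {
  d <- withr::local_tempdir()
  # s10 must sort after s2 despite lexicographic order
  for (nm in c("s0", "s1", "s2", "s10")) {
    m <- matrix(match(nm, c("s0", "s1", "s2", "s10")), 3, 4)
    tiff::writeTIFF(m / 255, file.path(d, paste0(nm, ".tif")), bits.per.sample = 8)
  }
  suppressWarnings(v <- read_volume(d))
  expect_identical(dim(v$data), c(4L, 3L, 4L) + 0L)
  expect_equal(v$data[, 1, 1], c(1, 2, 3, 4))
  expect_equal(natural_order(c("s0.tif", "s1.tif", "s10.tif", "s2.tif")),
               c(1L, 2L, 4L, 3L))
})

test_that("NRRD volumes preserve spacing and float data", {
  arr <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  v <- intensity_volume(arr, spacing = c(2, 1, 1))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$data, arr)
  expect_equal(vol_spacing(r), c(2, 1, 1))
})

test_that("spacing falls back to 1 with a warning, override wins", {
  v <- fx_small_volume()
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, f)
  expect_warning(r <- read_volume(f), "spacing")
  expect_equal(vol_spacing(r), c(1, 1, 1))
  expect_error(read_volume(f, spacing_override = c(0, 1, 1)), "positive")
})

test_that("label width rule: 16-bit below 65536 labels, 32-bit above", {
  lab <- label_volume(array(c(0L, 1L, 2L, 2L, 0L, 1L, 2L, 1L), c(2, 2, 2)))
  f16 <- withr::local_tempfile(fileext = ".tif")
  write_labels(lab, f16)
  expect_equal(tiff::readTIFF(f16, payload = FALSE)$bits.per.sample, 16)
  suppressWarnings(expect_identical(read_labels(f16)$data, lab$data))

  big <- label_volume(array(c(0L, 70000L, 1L, 70000L), c(1, 2, 2)))
  f32 <- withr::local_tempfile(fileext = ".tif")
  write_labels(big, f32)
  expect_equal(tiff::readTIFF(f32, payload = FALSE)$bits.per.sample, 32)
  suppressWarnings(expect_identical(read_labels(f32)$data, big$data))

  empty <- label_volume(array(0L, c(2, 3, 2)))
  fe <- withr::local_tempfile(fileext = ".tif")
  write_labels(empty, fe)
  suppressWarnings(expect_identical(read_labels(fe)$data, empty$data))
})

test_that("masks and labels round-trip through NRRD", {
  m <- binary_mask(array(c(TRUE, FALSE), c(2, 3, 4)))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(m, f)
  r <- read_volume(f)
  expect_true(all((r$data > 0) == m$data))
  lab <- label_volume(array(sample(0:70000, 24), c(2, 3, 4)))
  fl <- withr::local_tempfile(fileext = ".nrrd")
  write_labels(lab, fl)
  suppressWarnings(expect_identical(read_labels(fl)$data, lab$data))
})

test_that("unreadable paths and inconsistent slices raise errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.tif")), "no such file")
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 2, 2), file.path(d, "a0.tif"))
  tiff::writeTIFF(matrix(0, 3, 2), file.path(d, "a1.tif"))
  expect_error(suppressWarnings(read_volume(d)), "inconsistent")
})
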