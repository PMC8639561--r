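test_that("constructor enforces the series invariants", {
  expect_error(image_series(array(1, c(1, 4, 4)), dt = 1, pixel_size = 1),
               "at least 2 frames")
  expect_error(
    image_series(list(matrix(0, 4, 4), matrix(0, 4, 5)), dt = 1,
                 pixel_size = 1),
    "same height and width")
  bad <- array(0, c(3, 4, 4)); bad[2, 1, 1] <- NaN
  expect_error(image_series(bad, dt = 1, pixel_size = 1), "non-finite")
  expect_error(image_series(array(0, c(3, 4, 4)), dt = 0, pixel_size = 1))

  s <- image_series(lapply(1:10, function(i) matrix(i, 8, 8)),
                    dt = 0.04, pixel_size = 1e-6)
  expect_identical(dim(s), c(10L, 8L, 8L))
  expect_equal(s$frames[7, 3, 5], 7)
})

test_that("a multi-page TIFF round-trips bit-identically and in page order", {
  set.seed(4)
  fr <- array(sample(0:65535, 3 * 8 * 8, TRUE), c(3, 8, 8))
  s <- image_series(fr, dt = 0.1, pixel_size = 2e-6)
  path <- withr::local_tempfile(fileext = ".tif")
  save_series(s, path)
  back <- load_series(path, dt = 0.1, pixel_size = 2e-6)
  expect_identical(back$frames, s$frames)   # order A,B,C preserved exactly
  expect_equal(back$bit_depth, 16L)
})

test_that("a directory of zero-padded frames loads in filename order", {
  dir <- withr::local_tempdir()
  set.seed(5)
  frames <- lapply(1:12, function(i) matrix(sample(0:65535, 36, TRUE), 6, 6))
  # write deliberately out of creation order; filename order must win
  for (i in sample(12)) {
    tiff::writeTIFF(frames[[i]] / 65535,
                    file.path(dir, sprintf("frame_%03d.tif", i)),
                    bits.per.sample = 16L)
  }
  s <- load_series(dir, dt = 0.04, pixel_size = 1e-6)
  expect_identical(dim(s), c(12L, 6L, 6L))
  for (i in c(1, 7, 12)) expect_equal(s$frames[i, , ], frames[[i]] * 1.0)
  s2 <- load_series(dir, dt = 0.04, pixel_size = 1e-6)
  expect_identical(s2$frames, s$frames)
})

test_that("mixed-width frame numbering is rejected, not guessed", {
  dir <- withr::local_tempdir()
  for (nm in c("f_2.tif", "f_10.tif")) {
    tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dir, nm),
                    bits.per.sample = 16L)
  }
  expect_error(load_series(dir, dt = 1, pixel_size = 1), "zero-pad")
})

test_that("mixed frame sizes and unreadable inputs give named errors", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dir, "a_1.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(matrix(0.5, 6, 6), file.path(dir, "a_2.tif"),
                  bits.per.sample = 16L)
  expect_error(load_series(dir, dt = 1, pixel_size = 1), "mixed sizes")
  expect_error(load_series("no/such/path.tif", dt = 1, pixel_size = 1),
               "no/such/path.tif")
  bad <- file.path(dir, "broken")
  dir.create(bad)
  writeLines("not an image", file.path(bad, "x_1.tif"))
  writeLines("not an image", file.path(bad, "x_2.tif"))
  expect_error(load_series(bad, dt = 1, pixel_size = 1), "x_1.tif")
})

test_that("PNG frames load as raw counts (8-bit)", {
  dir <- withr::local_tempdir()
  set.seed(6)
  frames <- lapply(1:3, function(i) matrix(sample(0:255, 16, TRUE), 4, 4))
  for (i in 1:3) {
    png::writePNG(frames[[i]] / 255, file.path(dir, sprintf("p_%02d.png", i)))
  }
  s <- load_series(dir, dt = 1, pixel_size = 1)
  expect_equal(s$frames[2, , ], frames[[2]] * 1.0)
  expect_equal(s$bit_depth, 8L)
})

test_that("out-of-range pixel values refuse 16-bit storage", {
  s <- image_series(array(-1, c(2, 4, 4)), dt = 1, pixel_size = 1)
  expect_error(save_series(s, tempfile(fileext = ".tif")), "16-bit")
})
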