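test_that("reflectance calibration maps dark to 0, white to 1, midpoint to 0.5", {
  set.seed(11)
  d <- c(6L, 7L, 4L)
  dark <- array(runif(prod(d), 50, 150), d)
  white <- dark + array(runif(prod(d), 500, 1500), d)
  refs <- referencePair(white, dark)
  wl <- seq(500, by = 10, length.out = d[3L])

  asCube <- function(a) hyperCube(a, wl)
  expect_equal(max(abs(cubeData(calibrateReflectance(asCube(dark), refs)))),
               0)
  expect_equal(cubeData(calibrateReflectance(asCube(white), refs)),
               array(1, d), ignore_attr = TRUE)
  mid <- calibrateReflectance(asCube((dark + white) / 2), refs)
  expect_equal(cubeData(mid), array(0.5, d), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(isCalibrated(mid))
})

test_that("calibration inverts an affine distortion with matching references", {
  set.seed(12)
  d <- c(5L, 5L, 3L)
  refl <- array(runif(prod(d)), d)
  gain <- array(runif(prod(d), 800, 1200), d)
  offset <- array(runif(prod(d), 90, 110), d)
  raw <- hyperCube(refl * gain + offset, c(500, 600, 700))
  refs <- referencePair(white = gain + offset, dark = offset)
  out <- calibrateReflectance(raw, refs)
  expect_equal(cubeData(out), refl, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("calibration handles dead pixels, clipping and 2-D references", {
  d <- c(4L, 3L, 2L)
  dark <- array(100, d)
  white <- array(900, d)
  white[1, 1, ] <- 100                      # dead: white == dark
  raw <- array(500, d)
  raw[2, 1, ] <- 50                         # below dark -> clipped
  cube <- hyperCube(raw, c(500, 600))
  # 2 dead entries of 24 exceed the 5% QC threshold
  expect_warning(out <- calibrateReflectance(cube,
                                             referencePair(white, dark)),
                 "dead")
  expect_equal(cubeData(out)[1, 1, ], c(0, 0))
  expect_equal(cubeData(out)[2, 1, ], c(0, 0))
  expect_equal(attr(cubeData(out), "deadPixelCount"), 2)
  expect_equal(attr(cubeData(out), "clippedCount"), 2)
  expect_warning(calibrateReflectance(cube, referencePair(dark, dark)),
                 "dead")

  # 2-D cols x bands reference broadcasts along the scan axis
  ref2d <- matrix(900, d[2L], d[3L])
  dark2d <- matrix(100, d[2L], d[3L])
  out2 <- calibrateReflectance(cube, referencePair(ref2d, dark2d))
  expect_equal(cubeData(out2)[3, 2, 1], 0.5)

  expect_error(calibrateReflectance(cube,
    referencePair(array(1, c(2, 2, 2)), array(0, c(2, 2, 2)))), "shape")
  expect_error(calibrateReflectance(out, referencePair(white, dark)),
               "already calibrated")
})

test_that("calibration is idempotent-equivalent with unit references", {
  cube <- randomCube(5, 5, 3, seed = 3)
  refs <- referencePair(array(1, dim(cubeData(cube))),
                        array(0, dim(cubeData(cube))))
  raw <- hyperCube(cubeData(cube), wavelengths(cube))
  out <- calibrateReflectance(raw, refs)
  expect_equal(cubeData(out), cubeData(cube), ignore_attr = TRUE)
})

test_that("spectral crop keeps exactly the closed interval and composes", {
  cube <- hyperCube(array(seq_len(2 * 2 * 7), c(2, 2, 7)),
                    seq(400, 1000, by = 100))
  out <- cropSpectralRange(cube, 500, 800)
  expect_equal(wavelengths(out), c(500, 600, 700, 800))
  expect_equal(cubeData(out), cubeData(cube)[, , 2:5])

  expect_equal(cubeData(cropSpectralRange(cube, 0, Inf)), cubeData(cube))
  expect_error(cropSpectralRange(cube, 405, 490), "no bands")

  # crop(crop(x, A), B) == crop(x, A intersect B)
  a <- cropSpectralRange(cropSpectralRange(cube, 450, 950), 550, 850)
  b <- cropSpectralRange(cube, 550, 850)
  expect_equal(cubeData(a), cubeData(b))
  expect_equal(wavelengths(a), wavelengths(b))
})

test_that("crop band count on a uniform grid matches enumeration", {
  grid <- seq(898, 1751, length.out = 512)
  cube <- hyperCube(array(0, c(2, 2, 512)), grid)
  out <- cropSpectralRange(cube, 900, 1601)
  expect_equal(nBands(out), sum(grid >= 900 & grid <= 1601))
})

test_that("scan padding appends zero rows and is a no-op at current size", {
  cube <- randomCube(10, 6, 3, seed = 4)
  expect_identical(padScanLength(cube, 10), cube)
  out <- padScanLength(cube, 14)
  expect_equal(spatialDims(out), c(14L, 6L))
  expect_equal(cubeData(out)[1:10, , ], cubeData(cube))
  expect_true(all(cubeData(out)[11:14, , ] == 0))
  expect_error(padScanLength(cube, 5), "smaller")
})

test_that("HyperCube validity enforces its invariants", {
  expect_error(hyperCube(array(1, c(2, 2, 3)), c(500, 600)), "bands")
  expect_error(hyperCube(array(1, c(2, 2, 3)), c(500, 700, 600)),
               "increasing")
  expect_error(hyperCube(array(-1, c(2, 2, 2)), c(500, 600),
                         isCalibrated = TRUE), "negative")
})
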