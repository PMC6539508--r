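test_that("contrast image subtracts extreme-mean bands", {
  d <- c(5L, 5L)
  cube <- hyperCube(array(rep(c(0.2, 0.9, 0.5), each = prod(d)),
                          c(d, 3L)), c(500, 600, 700),
                    isCalibrated = TRUE)
  expect_equal(contrastImage(cube), matrix(0.7, d[1L], d[2L]))

  flat <- hyperCube(array(0.4, c(d, 3L)), c(500, 600, 700),
                    isCalibrated = TRUE)
  expect_equal(contrastImage(flat), matrix(0, d[1L], d[2L]))

  one <- hyperCube(array(0.4, c(d, 1L)), 500, isCalibrated = TRUE)
  expect_warning(z <- contrastImage(one), "single-band")
  expect_equal(z, matrix(0, d[1L], d[2L]))
})

test_that("contrast image beats any single band at foreground separation", {
  # every band carries the same strong illumination gradient; subtracting
  # the lowest-intensity band from the highest cancels it, so the Otsu
  # between-class variance of the contrast image must top every single
  # band image
  set.seed(31)
  n <- 40L
  mask <- threeSquareMask(n)
  gradient <- matrix(rep(seq(0, 1.2, length.out = n), each = n), n, n)
  bands <- lapply(c(0.3, 0.9, 0.5), function(level) {
    img <- gradient + 0.05 + rnorm(n * n, 0, 0.01)
    img[mask] <- img[mask] + level
    img
  })
  cube <- hyperCube(array(unlist(bands), c(n, n, 3L)), c(500, 600, 700),
                    isCalibrated = TRUE)
  # share of image variance explained by the true fg/bg partition
  crit <- function(img) {
    w1 <- mean(mask); w0 <- 1 - w1
    w0 * w1 * (mean(img[mask]) - mean(img[!mask]))^2 / var(as.vector(img))
  }
  cimg <- contrastImage(cube)
  expect_gte(crit(cimg), max(vapply(bands, crit, numeric(1L))) - 1e-12)
})

test_that("Otsu threshold equals a brute-force 256-candidate sweep", {
  set.seed(32)
  for (rep in 1:5) {
    img <- matrix(c(rnorm(300, 0.3, 0.05), rnorm(200, 0.7, 0.08)), 25, 20)
    thr <- otsuThreshold(img)
    # brute force: evaluate between-class variance at every bin edge
    v <- as.vector(img); lo <- min(v); hi <- max(v)
    idx <- pmin(256L, 1L + floor((v - lo) / (hi - lo) * 256))
    h <- tabulate(idx, 256L)
    centers <- lo + (1:256 - 0.5) * (hi - lo) / 256
    best <- -Inf; bestT <- NA
    for (t in 1:255) {
      w0 <- sum(h[1:t]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(h[1:t] * centers[1:t]) / w0
      mu1 <- sum(h[(t + 1):256] * centers[(t + 1):256]) / w1
      s <- w0 * w1 * (mu0 - mu1)^2
      if (s > best) { best <- s; bestT <- lo + t * (hi - lo) / 256 }
    }
    expect_equal(thr, bestT)
  }
})

test_that("binarization handles two-level, fixed and degenerate images", {
  img <- matrix(rep(c(0, 1), 18), 6, 6)
  expect_equal(unclass(binarizeImage(img)), img == 1, ignore_attr = TRUE)
  m <- binarizeImage(img, method = "fixed", threshold = 0.5)
  expect_equal(unclass(m), img > 0.5, ignore_attr = TRUE)
  expect_error(binarizeImage(matrix(0.4, 3, 3)), "degenerate")
  expect_error(binarizeImage(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("ROI extraction finds disjoint squares with areas and order", {
  mask <- threeSquareMask(40L, 10L)
  rois <- extractROIs(mask, minAreaPx = 50L)
  expect_length(rois, 3L)
  expect_equal(vapply(rois, roiArea, integer(1L)), rep(100L, 3L))
  expect_equal(vapply(rois, roiId, integer(1L)), 1:3)
  # reading order: two top squares (left then right), then bottom-left
  origins <- t(vapply(rois, function(r) roiBBox(r)[1:2], integer(2L)))
  expect_true(all(diff(origins[, 1L]) >= 0))
  expect_lt(origins[1L, 2L], origins[2L, 2L])
  expect_error(extractROIs(mask, minAreaPx = 101L), "largest observed: 100")
})

test_that("component labelling matches a brute-force flood fill", {
  set.seed(33)
  for (conn in c(8, 4)) {
    for (rep in 1:4) {
      mask <- matrix(runif(30 * 25) < 0.45, 30, 25)
      mask[1, 1] <- TRUE
      got <- hsifuse:::.labelComponents(mask, conn == 8)
      want <- bruteFloodFill(mask, conn == 8)
      # same partition: labels must be a bijection
      expect_equal(got > 0, want > 0)
      key <- paste(got[mask], want[mask])
      expect_equal(length(unique(key)), max(want))
    }
  }
})

test_that("mean spectrum equals naive accumulation and is linear", {
  cube <- randomCube(10, 9, 6, seed = 34)
  set.seed(35)
  mask <- matrix(runif(90) < 0.4, 10, 9)
  mask[1, 1] <- TRUE
  got <- meanSpectrum(cube, mask)
  want <- numeric(6)
  for (b in 1:6) {
    s <- 0
    for (r in 1:10) for (c in 1:9)
      if (mask[r, c]) s <- s + cubeData(cube)[r, c, b]
    want[b] <- s / sum(mask)
  }
  expect_equal(got, want, tolerance = 1e-12)

  cube2 <- randomCube(10, 9, 6, seed = 36)
  mix <- hyperCube(2 * cubeData(cube) + 3 * cubeData(cube2),
                   wavelengths(cube), isCalibrated = TRUE)
  expect_equal(meanSpectrum(mix, mask),
               2 * got + 3 * meanSpectrum(cube2, mask), tolerance = 1e-12)

  expect_error(meanSpectrum(cube, matrix(FALSE, 10, 9)), "empty")

  # constant cube -> constant spectrum
  const <- hyperCube(array(rep(c(0.1, 0.7), each = 90), c(10, 9, 2)),
                     c(500, 600), isCalibrated = TRUE)
  expect_equal(meanSpectrum(const, mask), c(0.1, 0.7))
})

test_that("ROI masks are disjoint, inside the foreground, and order-stable", {
  set.seed(37)
  cfg <- tinySceneConfig(seed = 5)
  sc <- generateScene(cfg)
  cal <- calibrateReflectance(sc$vnir, sc$vnirRefs)
  rois <- segmentSlices(cal, minAreaPx = 60)
  total <- Reduce(`+`, lapply(rois, function(r) roiMask(r) * 1L))
  expect_lte(max(total), 1L)
  gray <- contrastImage(cal)
  fg <- binarizeImage(gray)
  expect_true(all(fg[total == 1L]))
  # padding the cube does not change the extracted ROI set
  padded <- padScanLength(cal, spatialDims(cal)[1L] + 15L)
  roisP <- segmentSlices(padded, minAreaPx = 60)
  expect_length(roisP, length(rois))
  expect_equal(lapply(roisP, function(r) roiBBox(r)),
               lapply(rois, function(r) roiBBox(r)))
})
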