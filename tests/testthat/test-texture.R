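test_that("quantization maps in-mask intensities to 1..L", {
  img <- matrix(c(0, 0.5, 1, 9), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  q <- quantizeImage(img, mask, L = 4)
  expect_equal(q@levels[mask], c(1L, 3L, 4L))
  expect_equal(q@levels[!mask], 0L)

  # already 1..L integers with matching range pass through unchanged
  img2 <- matrix(c(1, 2, 3, 4), 2, 2)
  q2 <- quantizeImage(img2, matrix(TRUE, 2, 2), L = 4)
  expect_equal(q2@levels, matrix(1:4, 2, 2))

  set.seed(61)
  img3 <- matrix(rnorm(100), 10, 10)
  q3 <- quantizeImage(img3, matrix(TRUE, 10, 10), L = 7)
  expect_true(all(q3@levels >= 1 & q3@levels <= 7))

  expect_error(quantizeImage(matrix(1, 3, 3), matrix(TRUE, 3, 3), 4),
               "constant")
  expect_error(quantizeImage(img, matrix(FALSE, 2, 2), 4), "2 pixels")
})

test_that("GLCM features of a 4x4 checkerboard match hand enumeration", {
  board <- matrix(rep(c(1L, 2L), 8), 4, 4)
  board[, c(2, 4)] <- 3L - board[, c(2, 4)]
  q <- new("QuantizedImage", levels = board, L = 2L)
  f <- glcmFeatures(q)
  expect_equal(unname(f["contrast_0"]), 1)
  expect_equal(unname(f["dissimilarity_0"]), 1)
  expect_equal(unname(f["homogeneity_0"]), 0.5)
  expect_equal(unname(f["energy_0"]), sqrt(0.5), tolerance = 1e-5)
  expect_equal(unname(f["correlation_0"]), -1)
  expect_length(f, 20L)
})

test_that("constant-level ROI yields the degenerate GLCM convention", {
  q <- new("QuantizedImage", levels = matrix(2L, 4, 4), L = 4L)
  f <- glcmFeatures(q)
  expect_equal(unname(f[paste0("contrast_", c(0, 45, 90, 135))]),
               rep(0, 4))
  expect_equal(unname(f[paste0("homogeneity_", c(0, 45, 90, 135))]),
               rep(1, 4))
  expect_equal(unname(f[paste0("energy_", c(0, 45, 90, 135))]), rep(1, 4))
  expect_equal(unname(f[paste0("correlation_", c(0, 45, 90, 135))]),
               rep(0, 4))
})

test_that("GLCM equals brute-force pair counting on random masked images", {
  set.seed(62)
  offsets <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                  "135" = c(-1, -1))
  for (rep in 1:6) {
    img <- matrix(runif(64), 8, 8)
    mask <- matrix(runif(64) < 0.8, 8, 8)
    mask[3:6, 3:6] <- TRUE
    q <- quantizeImage(img, mask, L = 5)
    f <- glcmFeatures(q)
    for (a in names(offsets)) {
      P <- bruteGLCM(q@levels, 5L, offsets[[a]])
      want <- bruteGLCMStats(P)
      got <- f[paste0(names(want), "_", a)]
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
    }
  }
})

test_that("GLCM P is a symmetric distribution with bounded statistics", {
  set.seed(63)
  img <- matrix(runif(144), 12, 12)
  q <- quantizeImage(img, matrix(TRUE, 12, 12), L = 8)
  for (off in list(c(0, 1), c(-1, 1))) {
    P <- hsifuse:::.glcmMatrix(q@levels, 8L, off)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
  }
  f <- glcmFeatures(q)
  expect_true(all(f[grep("contrast|dissim", names(f))] >= 0))
  expect_true(all(f[grep("homog|energy", names(f))] > 0 &
                    f[grep("homog|energy", names(f))] <= 1))
  expect_true(all(abs(f[grep("correlation", names(f))]) <= 1))
})

test_that("GLRLM of simple patterns matches hand enumeration", {
  # constant 4x4, horizontal runs only: 4 runs of length 4
  runs <- hsifuse:::.runLengths(matrix(1L, 4, 4), "0")
  s <- hsifuse:::.glrlmStats(runs)
  expect_equal(unname(s), c(0.0625, 16, 4, 0.25, 4, 1, 1),
               ignore_attr = TRUE)

  # alternating single-pixel columns: all horizontal runs have length 1
  alt <- matrix(rep(c(1L, 2L), each = 4, times = 2), 4, 4)
  s2 <- hsifuse:::.glrlmStats(hsifuse:::.runLengths(alt, "0"))
  expect_equal(unname(s2[c("SRE", "LRE", "RP")]), c(1, 1, 1))
})

test_that("GLRLM equals brute-force run enumeration on random images", {
  set.seed(64)
  steps <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(1, 0),
                "135" = c(1, 1))
  for (rep in 1:6) {
    img <- matrix(runif(64), 8, 8)
    mask <- matrix(runif(64) < 0.85, 8, 8)
    mask[3:6, 3:6] <- TRUE
    q <- quantizeImage(img, mask, L = 4)
    want <- rowMeans(vapply(names(steps), function(a)
      bruteGLRLMStats(bruteRuns(q@levels, steps[[a]])), numeric(7L)))
    got <- glrlmFeatures(q)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("GLRLM conserves pixels and bounds its emphases", {
  set.seed(65)
  img <- matrix(runif(150), 15, 10)
  mask <- matrix(runif(150) < 0.7, 15, 10)
  mask[5:10, 4:8] <- TRUE
  q <- quantizeImage(img, mask, L = 6)
  for (a in c("0", "45", "90", "135")) {
    runs <- hsifuse:::.runLengths(q@levels, a)
    expect_equal(sum(runs[, 2L]), sum(mask))
    s <- hsifuse:::.glrlmStats(runs)
    expect_lte(s["SRE"], 1)
    expect_gte(s["LRE"], 1)
    expect_gt(s["RP"], 0); expect_lte(s["RP"], 1)
  }
})

test_that("both extractors ignore out-of-mask pixels", {
  set.seed(66)
  img <- matrix(runif(100), 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:8, 3:8] <- TRUE
  q1 <- quantizeImage(img, mask, L = 5)
  img2 <- img; img2[!mask] <- 99
  q2 <- quantizeImage(img2, mask, L = 5)
  expect_equal(glcmFeatures(q1), glcmFeatures(q2))
  expect_equal(glrlmFeatures(q1), glrlmFeatures(q2))
})

test_that("textureTable concatenates per-wavelength features in order", {
  cube <- randomCube(30, 30, 5, seed = 67)
  mask1 <- matrix(FALSE, 30, 30); mask1[2:12, 2:12] <- TRUE
  mask2 <- matrix(FALSE, 30, 30); mask2[16:28, 14:28] <- TRUE
  rois <- list(new("SliceROI", mask = mask1, bbox = c(2L, 2L, 13L, 13L),
                   areaPx = sum(mask1), roiId = 1L),
               new("SliceROI", mask = mask2, bbox = c(16L, 14L, 29L, 29L),
                   areaPx = sum(mask2), roiId = 2L))
  tabC <- textureTable(cube, rois, c(1L, 3L, 5L), method = "GLCM")
  expect_equal(dim(featureValues(tabC)), c(2L, 60L))
  tabR <- textureTable(cube, rois, c(2L, 4L), method = "GLRLM")
  expect_equal(dim(featureValues(tabR)), c(2L, 14L))
  # wavelength-major order: first 20 GLCM columns belong to band 1
  expect_true(all(grepl("^tex_500_", tabC@columnLabels[1:20])))
  # permuting ROI order permutes rows identically
  tabSwap <- textureTable(cube, rev(rois), c(1L, 3L, 5L), method = "GLCM")
  expect_equal(unname(featureValues(tabSwap)),
               unname(featureValues(tabC)[2:1, ]))
  expect_error(textureTable(cube, rois, 99L), "outside")
})
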