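test_that("block averaging brings both camera frames to 128 x 300", {
  # thin spectral axis keeps the full-frame geometry check cheap
  vnir <- hyperCube(array(runif(512 * 1200), c(512, 1200, 1)), 600,
                    isCalibrated = TRUE)
  swir <- hyperCube(array(runif(640 * 1500), c(640, 1500, 1)), 1200,
                    rangeTag = "SWIR", isCalibrated = TRUE)
  v4 <- blockAverage(vnir, c(4, 4))
  s5 <- blockAverage(swir, c(5, 5))
  expect_equal(spatialDims(v4), c(128L, 300L))
  expect_equal(spatialDims(s5), c(128L, 300L))
  # global per-band mean preserved (no trailing partial blocks here)
  expect_equal(mean(cubeData(v4)), mean(cubeData(vnir)), tolerance = 1e-12)
  expect_equal(mean(cubeData(s5)), mean(cubeData(swir)), tolerance = 1e-12)
})

test_that("block averaging drops trailing partial blocks and handles edge cases", {
  cube <- randomCube(10, 11, 2, seed = 101)
  out <- blockAverage(cube, c(4, 3))
  expect_equal(spatialDims(out), c(2L, 3L))
  # value check against direct mean of one block
  expect_equal(cubeData(out)[2, 3, 1],
               mean(cubeData(cube)[5:8, 7:9, 1]), tolerance = 1e-12)
  expect_equal(mean(cubeData(out)[, , 2]),
               mean(cubeData(cube)[1:8, 1:9, 2]), tolerance = 1e-12)

  const <- hyperCube(array(0.3, c(9, 9, 2)), c(500, 600),
                     isCalibrated = TRUE)
  expect_true(all(cubeData(blockAverage(const, c(3, 3))) == 0.3))
  expect_error(blockAverage(cube, c(20, 3)), "larger")
})

test_that("pixel classification labels endmember-pure pixels correctly", {
  set.seed(102)
  wl <- seq(500, by = 5, length.out = 40)
  means <- rbind(sin(wl / 40) + 2, cos(wl / 50) + 2, sin(wl / 25) + 1.5)
  Xtr <- means[rep(1:3, each = 15), ] + matrix(rnorm(45 * 40, 0, 0.02),
                                               45)
  y <- factor(rep(c("a", "b", "c"), each = 15))
  scaler <- autoscaleFit(Xtr)
  model <- plsdaFit(autoscaleApply(Xtr, scaler), y, nLatent = 3)

  cube <- hyperCube(array(rep(means[2, ], each = 36), c(6, 6, 40)), wl,
                    isCalibrated = TRUE)
  map <- classifyPixels(cube, model, preprocess = preprocessSpec("none"),
                        scaler = scaler,
                        backgroundMask = matrix(TRUE, 6, 6))
  expect_true(all(map@labels == 2L))

  empty <- classifyPixels(cube, model, preprocess = preprocessSpec("none"),
                          scaler = scaler,
                          backgroundMask = matrix(FALSE, 6, 6))
  expect_true(all(empty@labels == 0L))
  expect_error(classifyPixels(cube, model,
                              preprocess = preprocessSpec("none"),
                              scaler = scaler,
                              backgroundMask = matrix(TRUE, 3, 3)),
               "mask shape")
})

test_that("RGB rendering round-trips labels through a lossless PNG", {
  labels <- matrix(sample(0:3, 60, replace = TRUE), 6, 10)
  map <- new("ClassMap", labels = labels,
             classColors = c("#FF0000", "#00FF00", "#0000FF"),
             provenance = list())
  path <- file.path(withr::local_tempdir(), "map.png")
  renderRGB(map, path)
  back <- readClassMapPNG(path, map@classColors)
  expect_equal(back, labels)

  # label permutation permutes hues: rendering permuted labels with a
  # permuted palette gives the same image
  perm <- c(2L, 3L, 1L)
  permLabels <- labels
  permLabels[labels > 0] <- perm[labels[labels > 0]]
  path2 <- file.path(withr::local_tempdir(), "map2.png")
  renderRGB(new("ClassMap", labels = permLabels,
                classColors = map@classColors[order(perm)],
                provenance = list()), path2)
  expect_equal(png::readPNG(path2), png::readPNG(path))
})

test_that("synthetic-scene maps recover slice classes by majority vote", {
  cfg <- tinySceneConfig(seed = 9, signalSplit = "spectral_only")
  sc <- generateScene(cfg)
  cal <- calibrateReflectance(sc$vnir, sc$vnirRefs)
  rois <- segmentSlices(cal, minAreaPx = 60)
  spectra <- extractSpectra(cal, rois)
  truthLabels <- factor(sc$truth@sliceLabels)
  scaler <- autoscaleFit(spectra@values)
  model <- plsdaFit(autoscaleApply(spectra@values, scaler), truthLabels,
                    nLatent = 3)
  small <- blockAverage(cal, c(2, 2))
  map <- classifyPixels(small, model, preprocess = preprocessSpec("none"),
                        scaler = scaler)
  truthSmall <- sc$truth@pixelMapVNIR[seq(1, 2 * nrow(map@labels), by = 2),
                                      seq(1, 2 * ncol(map@labels), by = 2)]
  expect_equal(dim(truthSmall), dim(map@labels))
  # per-slice majority label must match the true class for >= 90% of slices
  idxMap <- sc$sliceIndexVNIR[seq(1, 2 * nrow(map@labels), by = 2),
                              seq(1, 2 * ncol(map@labels), by = 2)]
  ok <- vapply(seq_along(truthLabels), function(i) {
    lab <- map@labels[idxMap == i]
    lab <- lab[lab > 0]
    length(lab) > 0 &&
      as.integer(names(which.max(table(lab)))) ==
        as.integer(truthLabels[i])
  }, logical(1L))
  expect_gte(mean(ok), 0.9)
})
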