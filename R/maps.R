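#' @include AllClasses.R
#' @include segmentation.R
#' @include plsda.R
#' @include preprocess.R
NULL

#' Block-average spatial downsampling
#'
#' Replaces each non-overlapping h x w pixel block by its mean, per band.
#' Trailing rows/columns that do not fill a complete block are dropped, so
#' e.g. a 512 x 1200 frame averaged 4 x 4 and a 640 x 1500 frame averaged
#' 5 x 5 both land on a 128 x 300 grid — the device for bringing two
#' camera ranges of different native resolution to a common map grid.
#'
#' @param cube a [HyperCube-class].
#' @param block integer (h, w) block size; a scalar is used for both.
#' @return The downsampled [HyperCube-class] (pixel size scaled
#'   accordingly).
#' @export
blockAverage <- function(cube, block) {
  stopifnot(is(cube, "HyperCube"))
  block <- as.integer(rep_len(block, 2L))
  if (any(block < 1L)) stop("block dims must be >= 1")
  d <- dim(cube@data)
  nr <- d[1L] %/% block[1L]
  nc <- d[2L] %/% block[2L]
  if (nr < 1L || nc < 1L) stop("block larger than image")

  x <- cube@data[seq_len(nr * block[1L]), seq_len(nc * block[2L]), ,
                 drop = FALSE]
  # fold each spatial axis: (h, nr, w, nc, bands) -> mean over h and w
  x <- array(x, dim = c(block[1L], nr, nc * block[2L] * d[3L]))
  x <- colMeans(x)                                  # (nr, w*nc*bands)
  x <- array(x, dim = c(nr, block[2L], nc * d[3L]))
  x <- aperm(x, c(2L, 1L, 3L))
  x <- colMeans(x)                                  # (nr, nc*bands)
  out <- cube
  out@data <- array(x, dim = c(nr, nc, d[3L]))
  if (!is.na(cube@pixelSizeMm))
    out@pixelSizeMm <- cube@pixelSizeMm * block[1L]
  validObject(out)
  out
}

#' Pixel-wise classification map
#'
#' Applies a trained full-band PLS-DA model to every foreground pixel of a
#' (typically block-averaged) cube: each pixel spectrum is preprocessed
#' with the same recipe as the training spectra, scaled with the training
#' scaler, scored, and labelled by the argmax class. Background pixels are
#' 0. When no `backgroundMask` is given, the background is detected by
#' running the slice segmentation chain on the cube itself.
#'
#' @param cube a calibrated [HyperCube-class] on the model's band grid.
#' @param model a `"plsda"` fit from [plsdaFit()].
#' @param preprocess the [PreprocessSpec-class] used for the training
#'   spectra.
#' @param scaler the [autoscaleFit()] statistics used for training.
#' @param backgroundMask optional logical matrix, `TRUE` = foreground.
#' @param classColors hex colors per class (default red/green/blue).
#' @param mscReference MSC reference spectrum when the recipe is MSC.
#' @return A [ClassMap-class].
#' @export
classifyPixels <- function(cube, model, preprocess = preprocessSpec(),
                           scaler = NULL, backgroundMask = NULL,
                           classColors = NULL, mscReference = NULL) {
  stopifnot(is(cube, "HyperCube"))
  if (nBands(cube) != length(model$xCenter) && is.null(scaler))
    stop("cube band grid does not match the fitted model")
  if (is.null(backgroundMask)) {
    gray <- contrastImage(cube)
    backgroundMask <- binarizeImage(gray)
  }
  d <- dim(cube@data)
  if (!identical(dim(backgroundMask), d[1:2]))
    stop("background mask shape mismatch")

  labels <- matrix(0L, d[1L], d[2L])
  fg <- which(backgroundMask)
  if (length(fg)) {
    flat <- matrix(cube@data, d[1L] * d[2L], d[3L])
    spec <- flat[fg, , drop = FALSE]
    spec <- featureValuesOrMatrix(preprocessSpectra(
      spectrumTable(spec, cube@wavelengths), preprocess,
      reference = mscReference))
    if (!is.null(scaler)) spec <- autoscaleApply(spec, scaler)
    if (ncol(spec) != length(model$xCenter))
      stop("band grid after preprocessing does not match the model")
    pred <- plsdaPredict(model, spec)
    labels[fg] <- as.integer(pred$labels)
  }
  if (is.null(classColors)) {
    classColors <- if (length(model$levels) <= 3L)
      c("#FF0000", "#00FF00", "#0000FF")[seq_along(model$levels)]
    else grDevices::rainbow(length(model$levels))
  }
  new("ClassMap", labels = labels, classColors = classColors,
      provenance = list(model = "plsda", nLatent = model$nLatent))
}

featureValuesOrMatrix <- function(x) {
  if (is(x, "SpectrumTable")) x@values else as.matrix(x)
}

#' Render a class map as an RGB PNG
#'
#' Class k is drawn in its (by default pure primary) color; background is
#' black. PNG is lossless, so decoding the image recovers the label set
#' exactly.
#'
#' @param map a [ClassMap-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
renderRGB <- function(map, path) {
  stopifnot(is(map, "ClassMap"))
  pal <- grDevices::col2rgb(map@classColors) / 255
  lab <- map@labels
  img <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  for (k in seq_len(ncol(pal))) {
    sel <- lab == k
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- pal[ch, k]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Decode a rendered map back to labels
#'
#' Inverse of [renderRGB()] for round-trip checks: matches each pixel's
#' color against the palette.
#'
#' @param path PNG path written by [renderRGB()].
#' @param classColors the palette used at render time.
#' @return Integer label matrix (0 = background).
#' @export
readClassMapPNG <- function(path, classColors) {
  img <- png::readPNG(path)
  pal <- grDevices::col2rgb(classColors) / 255
  lab <- matrix(0L, dim(img)[1L], dim(img)[2L])
  for (k in seq_len(ncol(pal))) {
    hit <- abs(img[, , 1L] - pal[1L, k]) < 1e-3 &
      abs(img[, , 2L] - pal[2L, k]) < 1e-3 &
      abs(img[, , 3L] - pal[3L, k]) < 1e-3
    lab[hit] <- k
  }
  lab
}
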