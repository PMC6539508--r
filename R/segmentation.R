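#' @include AllClasses.R
NULL

#' Background-contrast image of a cube
#'
#' Builds a single gray-level image that maximizes the foreground/background
#' contrast by subtracting the band image of lowest overall intensity from
#' the band image of highest overall intensity. By default "lowest/highest
#' intensity" is judged at the band level via the spatial mean; with
#' `perPixel = TRUE` the per-pixel spectral max minus min is used instead.
#'
#' @param cube a calibrated [HyperCube-class].
#' @param perPixel take per-pixel spectral extremes instead of selecting two
#'   whole bands.
#' @return A numeric rows x cols matrix; values may be negative.
#' @seealso [binarizeImage()], [extractROIs()]
#' @export
contrastImage <- function(cube, perPixel = FALSE) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  if (perPixel)
    return(apply(cube@data, c(1L, 2L), max) - apply(cube@data, c(1L, 2L), min))
  if (d[3L] == 1L) {
    warning("single-band cube: contrast image is identically zero")
    return(matrix(0, d[1L], d[2L]))
  }
  bandMeans <- apply(cube@data, 3L, mean)
  cube@data[, , which.max(bandMeans)] - cube@data[, , which.min(bandMeans)]
}

#' Threshold a gray-level image to a foreground mask
#'
#' `method = "otsu"` picks the threshold maximizing the between-class
#' variance on a 256-bin histogram of the image; `method = "fixed"` uses the
#' supplied threshold. Foreground is strictly above the threshold.
#'
#' @param gray numeric matrix; all values finite.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value, required for `method = "fixed"`.
#' @return Logical matrix, `TRUE` = foreground. The chosen threshold is
#'   attached as attribute `"threshold"`.
#' @export
binarizeImage <- function(gray, method = c("otsu", "fixed"),
                          threshold = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(gray))) stop("image contains non-finite values")
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method requires a threshold")
    thr <- threshold
  } else {
    thr <- otsuThreshold(gray)
  }
  mask <- gray > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Otsu's threshold on a 256-bin histogram
#'
#' Bins the image range into 256 equal-width bins and returns the bin edge
#' maximizing the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} of the induced two-class split.
#' Computed with cumulative sums over the histogram (a single pass, not a
#' threshold-by-threshold sweep).
#'
#' @param gray finite numeric matrix or vector.
#' @return The threshold on the image's intensity scale.
#' @export
otsuThreshold <- function(gray) {
  v <- as.vector(gray)
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("degenerate (constant) image: Otsu undefined")
  nbins <- 256L
  # bin index 1..256; right edge inclusive in last bin
  idx <- pmin(nbins, 1L + floor((v - lo) / (hi - lo) * nbins))
  h <- tabulate(idx, nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins

  w0 <- cumsum(h)
  m0 <- cumsum(h * centers)
  total <- w0[nbins]; mTot <- m0[nbins]
  # candidate split after bin t: class 0 = bins 1..t
  t <- seq_len(nbins - 1L)
  w1 <- total - w0[t]
  valid <- w0[t] > 0 & w1 > 0
  crit <- rep(-Inf, nbins - 1L)
  crit[valid] <- (mTot * w0[t][valid] - total * m0[t][valid])^2 /
    (w0[t][valid] * w1[valid])
  best <- which.max(crit)
  lo + best * (hi - lo) / nbins  # upper edge of the best class-0 bin
}

#' Extract per-slice ROIs from a foreground mask
#'
#' Labels the connected components of the mask (4- or 8-connectivity),
#' discards components below `minAreaPx`, and returns the survivors as
#' [SliceROI-class] objects ordered in reading order: top-to-bottom, then
#' left-to-right by bounding-box origin. Components touching the image
#' border are kept.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param minAreaPx minimum component area in pixels.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal).
#' @return List of [SliceROI-class], `roiId` 1..n in reading order.
#' @export
extractROIs <- function(mask, minAreaPx = 200L, connectivity = c(8, 4)) {
  connectivity <- match.arg(as.character(connectivity[1L]), c("8", "4"))
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("mask is empty")

  labels <- .labelComponents(mask, connectivity == "8")
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= minAreaPx)
  if (!length(keep))
    stop("no component reaches minAreaPx = ", minAreaPx,
         " (largest observed: ", max(sizes), " px)")

  rois <- lapply(keep, function(k) {
    sel <- labels == k
    rows <- which(rowSums(sel) > 0)
    cols <- which(colSums(sel) > 0)
    new("SliceROI", mask = sel,
        bbox = as.integer(c(min(rows), min(cols),
                            max(rows) + 1L, max(cols) + 1L)),
        areaPx = as.integer(sum(sel)), roiId = 0L)
  })
  # reading order by bbox origin: top-to-bottom then left-to-right
  org <- t(vapply(rois, function(r) r@bbox[1:2], integer(2L)))
  ord <- order(org[, 1L], org[, 2L])
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]@roiId <- i
  rois
}

# Connected-component labelling via an adjacency graph over foreground
# pixels. Returns an integer matrix, 0 = background.
.labelComponents <- function(mask, diag8) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) return(matrix(0L, nr, nc))
  pixId <- matrix(0L, nr, nc)
  pixId[fg] <- seq_along(fg)

  edgePairs <- function(dr, dc) {
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    from <- fg[ok]
    to <- (c[ok] + dc - 1L) * nr + (r[ok] + dr)
    sel <- mask[to]
    cbind(pixId[from[sel]], pixId[to[sel]])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (diag8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offs, function(o) edgePairs(o[1L], o[2L])))

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  out <- matrix(0L, nr, nc)
  out[fg] <- as.integer(comp)
  out
}

#' Mean spectrum over an ROI
#'
#' Arithmetic mean of the cube over the ROI's pixels, one value per band.
#'
#' @param cube a [HyperCube-class].
#' @param roi a [SliceROI-class] (or a bare logical mask).
#' @return Numeric vector of length `nBands(cube)`.
#' @export
meanSpectrum <- function(cube, roi) {
  stopifnot(is(cube, "HyperCube"))
  mask <- if (is(roi, "SliceROI")) roi@mask else roi
  d <- dim(cube@data)
  if (!identical(dim(mask), d[1:2]))
    stop("ROI mask shape does not match cube spatial shape")
  n <- sum(mask)
  if (n == 0L) stop("empty ROI mask")
  flat <- matrix(cube@data, d[1L] * d[2L], d[3L])
  colSums(flat[as.vector(mask), , drop = FALSE]) / n
}

#' Mean-ROI spectra of a segmented cube
#'
#' Convenience wrapper building a [SpectrumTable-class] of one mean spectrum
#' per ROI, rows in `roiId` order.
#'
#' @param cube a [HyperCube-class].
#' @param rois list of [SliceROI-class] from [extractROIs()].
#' @param labels optional class labels, one per ROI.
#' @return A [SpectrumTable-class].
#' @export
extractSpectra <- function(cube, rois, labels = factor()) {
  vals <- t(vapply(rois, function(r) meanSpectrum(cube, r),
                   numeric(nBands(cube))))
  spectrumTable(vals, cube@wavelengths,
                sampleIds = paste0("roi", vapply(rois, roiId, integer(1L))),
                labels = labels)
}

#' Segment a calibrated cube into slice ROIs
#'
#' The standard chain: contrast image, Otsu (or fixed) binarization, then
#' connected-component ROI extraction.
#'
#' @param cube a calibrated [HyperCube-class].
#' @param minAreaPx minimum ROI area in pixels.
#' @param method threshold method, `"otsu"` or `"fixed"`.
#' @param threshold threshold for `method = "fixed"`.
#' @param connectivity 4 or 8.
#' @param perPixel see [contrastImage()].
#' @return List of [SliceROI-class].
#' @export
segmentSlices <- function(cube, minAreaPx = 200L,
                          method = c("otsu", "fixed"), threshold = NULL,
                          connectivity = 8, perPixel = FALSE) {
  gray <- contrastImage(cube, perPixel = perPixel)
  mask <- binarizeImage(gray, method = match.arg(method),
                        threshold = threshold)
  extractROIs(mask, minAreaPx = minAreaPx, connectivity = connectivity)
}

#' Write a mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' ROI bookkeeping table
#'
#' @param rois list of [SliceROI-class].
#' @return data.frame with roi_id, bbox coordinates and area_px, suitable
#'   for CSV export.
#' @export
roiTable <- function(rois) {
  data.frame(
    roi_id = vapply(rois, roiId, integer(1L)),
    row0 = vapply(rois, function(r) r@bbox[1L], integer(1L)),
    col0 = vapply(rois, function(r) r@bbox[2L], integer(1L)),
    row1 = vapply(rois, function(r) r@bbox[3L], integer(1L)),
    col1 = vapply(rois, function(r) r@bbox[4L], integer(1L)),
    area_px = vapply(rois, roiArea, integer(1L))
  )
}
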