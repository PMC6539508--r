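#' @include AllClasses.R
NULL

#' White/dark reflectance calibration
#'
#' Converts raw camera counts to relative reflectance using the standard
#' two-point normalization
#' \deqn{R_c = (R_{raw} - R_{dark}) / (R_{white} - R_{dark})}
#' applied elementwise. The white reference is a near-100%-reflective
#' target; the dark reference is taken with the shutter closed, capturing
#' the sensor dark current.
#'
#' Negative calibrated values (raw below dark, from noise) are clipped to 0.
#' Pixels where white equals dark carry no radiometric information; they are
#' set to 0 and counted as dead pixels. References may be 2-D
#' (cols x bands, a single reference line replicated along the scan axis)
#' or full 3-D arrays matching the cube.
#'
#' @param raw an uncalibrated [HyperCube-class] of counts.
#' @param refs a [ReferencePair-class] of white and dark references.
#' @return A calibrated [HyperCube-class]. Attributes `deadPixelCount`,
#'   `deadPixelFraction` and `clippedCount` on the returned object's
#'   `@data` report the QC tallies; a warning is raised when more than 5%
#'   of entries are dead.
#' @examples
#' raw <- hyperCube(array(500, c(4, 4, 2)), c(500, 600))
#' refs <- referencePair(array(900, c(4, 4, 2)), array(100, c(4, 4, 2)))
#' cal <- calibrateReflectance(raw, refs)
#' range(cubeData(cal))  # 0.5 everywhere
#' @export
calibrateReflectance <- function(raw, refs) {
  stopifnot(is(raw, "HyperCube"), is(refs, "ReferencePair"))
  if (isCalibrated(raw))
    stop("cube is already calibrated")
  d <- dim(raw@data)
  white <- .expandReference(refs@white, d)
  dark <- .expandReference(refs@dark, d)

  denom <- white - dark
  dead <- denom == 0
  nDead <- sum(dead)
  denom[dead] <- 1  # placeholder; dead entries forced to 0 below
  rc <- (raw@data - dark) / denom
  rc[dead] <- 0
  nClip <- sum(rc < 0)
  rc[rc < 0] <- 0

  attr(rc, "deadPixelCount") <- nDead
  attr(rc, "deadPixelFraction") <- nDead / length(rc)
  attr(rc, "clippedCount") <- nClip
  if (nDead / length(rc) > 0.05)
    warning(sprintf("%.1f%% of entries have white == dark (dead)",
                    100 * nDead / length(rc)))

  out <- raw
  out@data <- rc
  out@isCalibrated <- TRUE
  validObject(out)
  out
}

# Broadcast a 2-D (cols x bands) reference over the scan axis, or pass a
# matching 3-D array through. Any other shape is a dimension error.
.expandReference <- function(ref, d) {
  rd <- dim(ref)
  if (length(rd) == 3L) {
    if (!identical(as.integer(rd), as.integer(d)))
      stop("reference shape ", paste(rd, collapse = "x"),
           " does not match cube shape ", paste(d, collapse = "x"))
    return(ref)
  }
  if (length(rd) == 2L) {
    if (!identical(as.integer(rd), as.integer(d[2:3])))
      stop("2-D reference must be cols x bands (",
           d[2L], "x", d[3L], "), got ", paste(rd, collapse = "x"))
    return(aperm(array(ref, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L)))
  }
  stop("reference must be a 2-D matrix or 3-D array")
}

#' Crop a cube to a closed wavelength interval
#'
#' Keeps exactly the bands whose center wavelength lies in
#' `[loNm, hiNm]` (inclusive on both ends); data and wavelength vector stay
#' aligned. Used to discard low signal-to-noise shoulders of a camera range
#' (e.g. keeping 435-898 nm of a VNIR capture).
#'
#' @param cube a [HyperCube-class].
#' @param loNm,hiNm interval endpoints in nm, `loNm < hiNm`.
#' @return The cropped [HyperCube-class].
#' @examples
#' cube <- hyperCube(array(1, c(2, 2, 7)), seq(400, 1000, by = 100))
#' wavelengths(cropSpectralRange(cube, 500, 800))
#' @export
cropSpectralRange <- function(cube, loNm, hiNm) {
  stopifnot(is(cube, "HyperCube"), loNm < hiNm)
  keep <- which(cube@wavelengths >= loNm & cube@wavelengths <= hiNm)
  if (!length(keep))
    stop("no bands fall inside [", loNm, ", ", hiNm, "] nm")
  out <- cube
  out@data <- cube@data[, , keep, drop = FALSE]
  out@wavelengths <- cube@wavelengths[keep]
  validObject(out)
  out
}

#' Pad a cube along the scan axis
#'
#' Line-scan acquisitions of different physical lengths yield cubes of
#' different row counts; padding appends zero-valued (dark background) rows
#' at the scan end so all cubes in a batch share a frame. Mask-aware
#' downstream stages (segmentation, ROI statistics) ignore the padding
#' because it is background.
#'
#' @param cube a [HyperCube-class].
#' @param targetRows desired row count, at least the current one.
#' @return The padded [HyperCube-class].
#' @export
padScanLength <- function(cube, targetRows) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  targetRows <- as.integer(targetRows)
  if (targetRows < d[1L])
    stop("targetRows (", targetRows, ") smaller than current rows (",
         d[1L], ")")
  if (targetRows == d[1L]) return(cube)
  out <- cube
  padded <- array(0, dim = c(targetRows, d[2L], d[3L]))
  padded[seq_len(d[1L]), , ] <- cube@data
  out@data <- padded
  validObject(out)
  out
}
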