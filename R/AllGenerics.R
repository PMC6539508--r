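#' @include AllClasses.R
NULL

# ---- generics -------------------------------------------------------------

#' Accessors for hsifuse data objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `cubeData()` the 3-D array, `wavelengths()` the band-center grid in nm,
#' `rangeTag()` the camera-range tag, `isCalibrated()` the calibration flag,
#' `nBands()` / `spatialDims()` cube geometry, `featureValues()` the numeric
#' matrix of a table or block, `sampleIds()` row identifiers and
#' `classLabels()` the label factor.
#'
#' @param x an hsifuse object.
#' @return The corresponding slot value (see Description).
#' @name accessors
#' @aliases cubeData wavelengths rangeTag isCalibrated nBands spatialDims
#'   featureValues sampleIds classLabels
#' @examples
#' cube <- hyperCube(array(0.5, c(2, 2, 3)), c(500, 600, 700),
#'                   isCalibrated = TRUE)
#' spatialDims(cube); wavelengths(cube)
NULL

#' @rdname accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("rangeTag", function(x) standardGeneric("rangeTag"))
#' @rdname accessors
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))
#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))
#' @rdname accessors
#' @export
setGeneric("spatialDims", function(x) standardGeneric("spatialDims"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

# ---- HyperCube ------------------------------------------------------------

#' @rdname accessors
setMethod("cubeData", "HyperCube", function(x) x@data)
#' @rdname accessors
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "SpectrumTable", function(x) x@wavelengths)
#' @rdname accessors
setMethod("rangeTag", "HyperCube", function(x) x@rangeTag)
#' @rdname accessors
setMethod("isCalibrated", "HyperCube", function(x) x@isCalibrated)
#' @rdname accessors
setMethod("nBands", "HyperCube", function(x) dim(x@data)[3L])
#' @rdname accessors
setMethod("spatialDims", "HyperCube", function(x) dim(x@data)[1:2])

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  wl <- object@wavelengths
  cat(sprintf("HyperCube [%s]: %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              object@rangeTag, d[1L], d[2L], d[3L],
              min(wl), max(wl),
              if (object@isCalibrated) "calibrated reflectance" else "raw counts"))
  if (!is.na(object@pixelSizeMm))
    cat(sprintf("  pixel size: %.3g mm\n", object@pixelSizeMm))
})

# ---- SliceROI -------------------------------------------------------------

#' ROI accessors
#' @param x a [SliceROI-class].
#' @return `roiMask()` the logical mask, `roiBBox()` the half-open bounding
#'   box (row0, col0, row1, col1), `roiArea()` the pixel count, `roiId()`
#'   the reading-order ordinal.
#' @name roi-accessors
#' @aliases roiMask roiBBox roiArea roiId
NULL

#' @rdname roi-accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname roi-accessors
#' @export
setGeneric("roiBBox", function(x) standardGeneric("roiBBox"))
#' @rdname roi-accessors
#' @export
setGeneric("roiArea", function(x) standardGeneric("roiArea"))
#' @rdname roi-accessors
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @rdname roi-accessors
setMethod("roiMask", "SliceROI", function(x) x@mask)
#' @rdname roi-accessors
setMethod("roiBBox", "SliceROI", function(x) x@bbox)
#' @rdname roi-accessors
setMethod("roiArea", "SliceROI", function(x) x@areaPx)
#' @rdname roi-accessors
setMethod("roiId", "SliceROI", function(x) x@roiId)

setMethod("show", "SliceROI", function(object) {
  b <- object@bbox
  cat(sprintf("SliceROI #%d: %d px, bbox rows [%d,%d) cols [%d,%d)\n",
              object@roiId, object@areaPx, b[1L], b[3L], b[2L], b[4L]))
})

# ---- tables and blocks ----------------------------------------------------

#' @rdname accessors
setMethod("featureValues", "SpectrumTable", function(x) x@values)
#' @rdname accessors
setMethod("featureValues", "FeatureBlock", function(x) x@values)
#' @rdname accessors
setMethod("featureValues", "FusedFeatures", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "SpectrumTable", function(x) x@sampleIds)
#' @rdname accessors
setMethod("sampleIds", "FeatureBlock", function(x) x@sampleIds)
#' @rdname accessors
setMethod("sampleIds", "FusedFeatures", function(x) x@sampleIds)
#' @rdname accessors
setMethod("classLabels", "SpectrumTable", function(x) x@labels)

setMethod("show", "SpectrumTable", function(object) {
  cat(sprintf("SpectrumTable: %d samples x %d bands (%.1f-%.1f nm)%s\n",
              nrow(object@values), ncol(object@values),
              min(object@wavelengths), max(object@wavelengths),
              if (length(object@labels))
                sprintf(", %d classes", nlevels(object@labels)) else ""))
})

setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock [%s]: %d samples x %d features\n",
              object@blockTag, nrow(object@values), ncol(object@values)))
})

setMethod("show", "FusedFeatures", function(object) {
  cat(sprintf("FusedFeatures (%s): %d samples x %d columns\n",
              paste(object@provenance, collapse = " + "),
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "SelectedWavelengths", function(object) {
  cat(sprintf("SelectedWavelengths: %d bands, CV error %.3f\n",
              length(object@bandIndices), object@cvError))
  cat("  ", paste(format(object@wavelengthsNm), collapse = ", "), " nm\n",
      sep = "")
})

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport [%s]\n", object@modelSpec$type))
  cat(sprintf("  accuracy: calibration %.1f%%, prediction %.1f%%\n",
              object@accuracyCal, object@accuracyPre))
  if (length(object@aucMacro))
    cat(sprintf("  macro AUC: %.3f\n", object@aucMacro))
  if (length(object@cvSummary))
    cat(sprintf("  CV accuracy: %.1f%% +/- %.1f%% (%d folds)\n",
                100 * object@cvSummary$mean, 100 * object@cvSummary$sd,
                object@cvSummary$nFolds))
})

setMethod("show", "ClassMap", function(object) {
  tab <- table(factor(object@labels,
                      levels = 0:length(object@classColors)))
  cat(sprintf("ClassMap: %d x %d pixels; background %d, per-class: %s\n",
              nrow(object@labels), ncol(object@labels), tab[1L],
              paste(tab[-1L], collapse = ", ")))
})
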