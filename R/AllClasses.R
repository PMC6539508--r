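#' @import methods
NULL

#' HyperCube: a hyperspectral reflectance data-cube
#'
#' The central container of the package: a 3-D array of intensities or
#' reflectances with shape (rows, cols, bands), a wavelength vector in nm
#' giving the band centers, a camera-range tag, the spatial pixel size and a
#' calibration flag. Rows run along the scan (stage travel) direction.
#'
#' @slot data 3-D numeric array (rows, cols, bands); raw counts before
#'   calibration, dimensionless reflectance after.
#' @slot wavelengths numeric vector of band centers in nm, strictly
#'   increasing, one per band.
#' @slot rangeTag character, `"VNIR"` or `"SWIR"`.
#' @slot pixelSizeMm numeric scalar, mm per pixel (isotropic).
#' @slot isCalibrated logical; when `TRUE` all values are finite and >= 0.
#'
#' @seealso [hyperCube()], [calibrateReflectance()], [cropSpectralRange()]
#' @export
setClass("HyperCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    rangeTag = "character",
    pixelSizeMm = "numeric",
    isCalibrated = "logical"
  ),
  prototype(
    rangeTag = "VNIR",
    pixelSizeMm = NA_real_,
    isCalibrated = FALSE
  )
)

setValidity("HyperCube", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msgs <- c(msgs, "data must be a 3-D array (rows, cols, bands)")
  else if (length(object@wavelengths) != d[3L])
    msgs <- c(msgs, sprintf("length(wavelengths) [%d] != bands [%d]",
                            length(object@wavelengths), d[3L]))
  if (length(object@wavelengths) > 1L &&
      any(diff(object@wavelengths) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (!object@rangeTag %in% c("VNIR", "SWIR"))
    msgs <- c(msgs, "rangeTag must be 'VNIR' or 'SWIR'")
  if (isTRUE(object@isCalibrated)) {
    if (any(!is.finite(object@data)))
      msgs <- c(msgs, "calibrated cube contains non-finite values")
    else if (any(object@data < 0))
      msgs <- c(msgs, "calibrated cube contains negative reflectance")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HyperCube
#'
#' @param data 3-D numeric array (rows, cols, bands).
#' @param wavelengths numeric vector of band centers in nm.
#' @param rangeTag `"VNIR"` or `"SWIR"`.
#' @param pixelSizeMm spatial pixel size in mm (optional).
#' @param isCalibrated logical calibration flag.
#' @return A [HyperCube-class] object.
#' @examples
#' cube <- hyperCube(array(runif(4 * 5 * 3), c(4, 5, 3)),
#'                   wavelengths = c(500, 600, 700), isCalibrated = TRUE)
#' nBands(cube)
#' @export
hyperCube <- function(data, wavelengths, rangeTag = "VNIR",
                      pixelSizeMm = NA_real_, isCalibrated = FALSE) {
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      rangeTag = rangeTag, pixelSizeMm = pixelSizeMm,
      isCalibrated = isCalibrated)
}

#' ReferencePair: white and dark reference images
#'
#' Holds the white (near-100% reflective target) and dark (shutter closed)
#' reference measurements used for reflectance calibration. Each may be a
#' 2-D matrix (cols x bands, one reference line replicated along the scan) or
#' a 3-D array matching the raw cube geometry.
#'
#' @slot white numeric matrix or array, the white reference.
#' @slot dark numeric matrix or array of identical shape, the dark reference.
#' @seealso [calibrateReflectance()]
#' @export
setClass("ReferencePair",
  representation(white = "array", dark = "array"))

setValidity("ReferencePair", function(object) {
  if (!identical(dim(object@white), dim(object@dark)))
    return("white and dark references must have identical shape")
  TRUE
})

#' Construct a ReferencePair
#' @param white,dark numeric matrices or 3-D arrays of identical shape.
#' @return A [ReferencePair-class] object.
#' @export
referencePair <- function(white, dark) {
  new("ReferencePair", white = as.array(white), dark = as.array(dark))
}

#' SliceROI: one segmented slice within a cube
#'
#' @slot mask logical matrix over the cube's spatial grid; `TRUE` inside the
#'   slice.
#' @slot bbox integer vector (row0, col0, row1, col1), half-open on the
#'   high side.
#' @slot areaPx integer, number of `TRUE` mask pixels.
#' @slot roiId integer ordinal, assigned in reading order (top-to-bottom,
#'   then left-to-right by bounding-box origin).
#' @seealso [extractROIs()]
#' @export
setClass("SliceROI",
  representation(mask = "matrix", bbox = "integer",
                 areaPx = "integer", roiId = "integer"))

setValidity("SliceROI", function(object) {
  msgs <- character()
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  if (length(object@bbox) != 4L)
    msgs <- c(msgs, "bbox must be (row0, col0, row1, col1)")
  if (sum(object@mask) != object@areaPx)
    msgs <- c(msgs, "areaPx != number of TRUE mask pixels")
  if (length(msgs) == 0L) {
    b <- object@bbox
    out <- object@mask
    out[seq(b[1L], b[3L] - 1L), seq(b[2L], b[4L] - 1L)] <- FALSE
    if (any(out)) msgs <- c(msgs, "mask extends outside bbox")
  }
  if (length(msgs)) msgs else TRUE
})

#' SpectrumTable: per-sample mean spectra
#'
#' A samples x bands matrix of mean-ROI spectra, together with the wavelength
#' grid, sample identifiers and (optionally) class labels.
#'
#' @slot values numeric matrix, samples x bands.
#' @slot wavelengths numeric vector in nm, one per column.
#' @slot sampleIds character vector of row identifiers.
#' @slot labels factor of class labels, or zero-length if unlabelled.
#' @seealso [extractSpectra()], [preprocessSpectra()]
#' @export
setClass("SpectrumTable",
  representation(values = "matrix", wavelengths = "numeric",
                 sampleIds = "character", labels = "factor"))

setValidity("SpectrumTable", function(object) {
  msgs <- character()
  if (ncol(object@values) != length(object@wavelengths))
    msgs <- c(msgs, "ncol(values) != length(wavelengths)")
  if (nrow(object@values) != length(object@sampleIds))
    msgs <- c(msgs, "nrow(values) != length(sampleIds)")
  if (length(object@labels) && length(object@labels) != nrow(object@values))
    msgs <- c(msgs, "labels length must match rows")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectrumTable
#' @param values samples x bands numeric matrix.
#' @param wavelengths numeric vector in nm.
#' @param sampleIds character row identifiers (default "s1", "s2", ...).
#' @param labels optional class labels (coerced to factor).
#' @return A [SpectrumTable-class] object.
#' @export
spectrumTable <- function(values, wavelengths,
                          sampleIds = paste0("s", seq_len(nrow(values))),
                          labels = factor()) {
  new("SpectrumTable", values = as.matrix(values),
      wavelengths = as.numeric(wavelengths),
      sampleIds = as.character(sampleIds), labels = as.factor(labels))
}

#' PreprocessSpec: a spectral preprocessing recipe
#'
#' @slot method one of `"none"`, `"snv"`, `"msc"`, `"sg_smooth"`, `"d1"`,
#'   `"d2"`.
#' @slot sgWindow odd Savitzky-Golay window length (points).
#' @slot sgPolyorder Savitzky-Golay polynomial order.
#' @seealso [preprocessSpectra()]
#' @export
setClass("PreprocessSpec",
  representation(method = "character", sgWindow = "integer",
                 sgPolyorder = "integer"),
  prototype(method = "d2", sgWindow = 17L, sgPolyorder = 3L))

setValidity("PreprocessSpec", function(object) {
  msgs <- character()
  if (!object@method %in% c("none", "snv", "msc", "sg_smooth", "d1", "d2"))
    msgs <- c(msgs, "unknown preprocessing method")
  if (object@sgWindow %% 2L == 0L)
    msgs <- c(msgs, "sgWindow must be odd")
  if (object@sgWindow <= object@sgPolyorder)
    msgs <- c(msgs, "sgWindow must exceed sgPolyorder")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PreprocessSpec
#' @param method preprocessing method name.
#' @param sgWindow odd window length for Savitzky-Golay operations.
#' @param sgPolyorder polynomial order (default 3).
#' @return A [PreprocessSpec-class] object.
#' @export
preprocessSpec <- function(method = c("d2", "none", "snv", "msc",
                                      "sg_smooth", "d1"),
                           sgWindow = 17L, sgPolyorder = 3L) {
  method <- match.arg(method)
  new("PreprocessSpec", method = method, sgWindow = as.integer(sgWindow),
      sgPolyorder = as.integer(sgPolyorder))
}

#' SpaChain: one successive-projections candidate chain
#'
#' @slot startIndex integer, the seed column (1-based).
#' @slot indices integer vector of selected band indices in selection order.
#' @slot projectedNorms numeric, the projected Euclidean norm of each chosen
#'   column at its selection step; non-increasing.
#' @seealso [spaChain()]
#' @export
setClass("SpaChain",
  representation(startIndex = "integer", indices = "integer",
                 projectedNorms = "numeric"))

setValidity("SpaChain", function(object) {
  msgs <- character()
  if (anyDuplicated(object@indices))
    msgs <- c(msgs, "chain indices must be distinct")
  if (length(object@projectedNorms) != length(object@indices))
    msgs <- c(msgs, "one projected norm per index required")
  if (length(object@projectedNorms) > 1L &&
      any(diff(object@projectedNorms) > 1e-8 * object@projectedNorms[1L]))
    msgs <- c(msgs, "projected norms must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' SelectedWavelengths: the effective-wavelength subset chosen by SPA
#'
#' @slot bandIndices sorted integer band indices (1-based).
#' @slot wavelengthsNm matching wavelengths in nm.
#' @slot cvError cross-validated misclassification rate of the subset.
#' @slot chainProvenance integer (startIndex, chainLength) of the winning
#'   chain prefix.
#' @seealso [spaSelect()]
#' @export
setClass("SelectedWavelengths",
  representation(bandIndices = "integer", wavelengthsNm = "numeric",
                 cvError = "numeric", chainProvenance = "integer"))

setValidity("SelectedWavelengths", function(object) {
  msgs <- character()
  if (is.unsorted(object@bandIndices, strictly = TRUE))
    msgs <- c(msgs, "bandIndices must be sorted ascending")
  if (length(object@bandIndices) != length(object@wavelengthsNm))
    msgs <- c(msgs, "indices and wavelengths lengths differ")
  if (object@cvError < 0 || object@cvError > 1)
    msgs <- c(msgs, "cvError must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' QuantizedImage: a gray-level image restricted to an ROI
#'
#' In-mask pixels carry integer levels 1..L; pixels outside the mask are 0.
#'
#' @slot levels integer matrix; 0 = outside mask.
#' @slot L integer, number of gray levels.
#' @seealso [quantizeImage()], [glcmFeatures()], [glrlmFeatures()]
#' @export
setClass("QuantizedImage",
  representation(levels = "matrix", L = "integer"))

setValidity("QuantizedImage", function(object) {
  inmask <- object@levels[object@levels > 0L]
  if (length(inmask) && (min(inmask) < 1L || max(inmask) > object@L))
    return("in-mask levels must lie in 1..L")
  TRUE
})

#' FeatureBlock: one source-tagged feature matrix
#'
#' The unit of fusion: a samples x features matrix tagged by its source
#' (camera range x modality).
#'
#' @slot values numeric matrix, samples x features.
#' @slot blockTag one of `"VNIR_spec"`, `"SWIR_spec"`, `"VNIR_tex"`,
#'   `"SWIR_tex"`.
#' @slot columnLabels character, one per column.
#' @slot sampleIds character, one per row.
#' @seealso [featureBlock()], [fuseBlocks()]
#' @export
setClass("FeatureBlock",
  representation(values = "matrix", blockTag = "character",
                 columnLabels = "character", sampleIds = "character"))

setValidity("FeatureBlock", function(object) {
  msgs <- character()
  if (!object@blockTag %in% c("VNIR_spec", "SWIR_spec", "VNIR_tex", "SWIR_tex"))
    msgs <- c(msgs, "unknown blockTag")
  if (length(object@columnLabels) != ncol(object@values))
    msgs <- c(msgs, "one column label per column required")
  if (length(object@sampleIds) != nrow(object@values))
    msgs <- c(msgs, "one sample id per row required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureBlock
#' @param values samples x features numeric matrix.
#' @param blockTag source tag (`"VNIR_spec"`, `"SWIR_spec"`, `"VNIR_tex"`,
#'   `"SWIR_tex"`).
#' @param columnLabels optional column labels.
#' @param sampleIds optional row identifiers.
#' @return A [FeatureBlock-class] object.
#' @export
featureBlock <- function(values, blockTag,
                         columnLabels = colnames(values),
                         sampleIds = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(columnLabels))
    columnLabels <- paste0(blockTag, "_f", seq_len(ncol(values)))
  if (is.null(sampleIds))
    sampleIds <- paste0("s", seq_len(nrow(values)))
  new("FeatureBlock", values = values, blockTag = blockTag,
      columnLabels = as.character(columnLabels),
      sampleIds = as.character(sampleIds))
}

#' FusedFeatures: column-wise concatenation of autoscaled blocks
#'
#' @slot values samples x (sum of block widths) matrix of autoscaled
#'   features.
#' @slot provenance ordered character vector of the fused block tags.
#' @slot scaler per-column centering/scaling statistics learned on the
#'   calibration rows (list with `center`, `scale`, `constant`).
#' @slot columnLabels character column labels.
#' @slot sampleIds character row identifiers.
#' @seealso [fuseBlocks()]
#' @export
setClass("FusedFeatures",
  representation(values = "matrix", provenance = "character",
                 scaler = "list", columnLabels = "character",
                 sampleIds = "character"))

#' ModelReport: evaluation summary for one pipeline configuration
#'
#' @slot accuracyCal calibration-set accuracy, percent.
#' @slot accuracyPre prediction-set accuracy, percent.
#' @slot confusion classes x classes count matrix (rows = truth) on the
#'   prediction set.
#' @slot aucPerClass named numeric, one-vs-rest AUC per class.
#' @slot aucMacro unweighted mean of the per-class AUCs.
#' @slot modelSpec list describing the model (type and hyperparameters).
#' @slot cvSummary list with mean/sd accuracy over the repeated CV folds.
#' @export
setClass("ModelReport",
  representation(accuracyCal = "numeric", accuracyPre = "numeric",
                 confusion = "matrix", aucPerClass = "numeric",
                 aucMacro = "numeric", modelSpec = "list",
                 cvSummary = "list"))

setValidity("ModelReport", function(object) {
  msgs <- character()
  if (length(object@aucPerClass) &&
      (any(object@aucPerClass < 0) || any(object@aucPerClass > 1)))
    msgs <- c(msgs, "per-class AUC must lie in [0, 1]")
  if (length(object@confusion) && nrow(object@confusion)) {
    acc <- 100 * sum(diag(object@confusion)) / sum(object@confusion)
    if (abs(acc - object@accuracyPre) > 1e-8)
      msgs <- c(msgs, "prediction accuracy inconsistent with confusion trace")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClassMap: a pixel-wise classification map
#'
#' @slot labels integer matrix of class labels; 0 = background.
#' @slot classColors character vector of hex colors, one per class.
#' @slot provenance list recording the model id and block size used.
#' @seealso [classifyPixels()], [renderRGB()]
#' @export
setClass("ClassMap",
  representation(labels = "matrix", classColors = "character",
                 provenance = "list"))

setValidity("ClassMap", function(object) {
  lab <- object@labels
  if (any(lab < 0L) || any(lab > length(object@classColors)))
    return("labels must lie in 0..n_classes")
  TRUE
})

#' SceneConfig: parameters of the synthetic two-range scene generator
#'
#' Describes a scene of elliptical slices of several classes on a dark
#' background, imaged by two co-located cameras (VNIR-like and SWIR-like)
#' at different spatial resolutions. Class identity can be carried by the
#' spectral band shapes, by the spatial texture, or split between the two.
#'
#' @slot nClasses number of classes.
#' @slot slicesPerClass slices of each class placed per scene.
#' @slot vnirShape,swirShape integer (rows, cols) spatial frames.
#' @slot vnirGrid,swirGrid wavelength grids in nm.
#' @slot vnirPixelMm,swirPixelMm pixel sizes in mm.
#' @slot endmembers list, per class, of data frames (center, width, depth)
#'   of Gaussian absorption bands.
#' @slot baseline baseline reflectance of the flat endmember.
#' @slot scatterMultSd log-normal sd of the per-pixel multiplicative
#'   scatter factor.
#' @slot scatterAddSd sd of the per-pixel additive offset.
#' @slot textureCorrLen numeric, per class, spatial correlation length of
#'   the texture field in pixels (VNIR scale).
#' @slot textureSd relative sd of the unit-mean texture field.
#' @slot noiseSd additive per-pixel-per-band noise sd.
#' @slot signalSplit `"spectral_only"`, `"texture_only"` or `"both"`.
#' @slot seed integer random seed.
#' @seealso [sceneConfig()], [generateScene()]
#' @export
setClass("SceneConfig",
  representation(nClasses = "integer", slicesPerClass = "integer",
                 vnirShape = "integer", swirShape = "integer",
                 vnirGrid = "numeric", swirGrid = "numeric",
                 vnirPixelMm = "numeric", swirPixelMm = "numeric",
                 endmembers = "list", baseline = "numeric",
                 scatterMultSd = "numeric", scatterAddSd = "numeric",
                 textureCorrLen = "numeric", textureSd = "numeric",
                 noiseSd = "numeric", signalSplit = "character",
                 seed = "integer"))

setValidity("SceneConfig", function(object) {
  msgs <- character()
  if (!object@signalSplit %in% c("spectral_only", "texture_only", "both"))
    msgs <- c(msgs, "signalSplit must be spectral_only, texture_only or both")
  if (any(diff(object@vnirGrid) <= 0) || any(diff(object@swirGrid) <= 0))
    msgs <- c(msgs, "wavelength grids must be strictly increasing")
  if (any(object@textureCorrLen <= 0))
    msgs <- c(msgs, "texture correlation lengths must be positive")
  depths <- unlist(lapply(object@endmembers, function(e) e$depth))
  if (length(depths) && (any(depths <= 0) || any(depths >= 1)))
    msgs <- c(msgs, "absorption depths must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' GroundTruth: the known structure behind a synthetic scene
#'
#' @slot sliceLabels integer class label per slice, in reading order.
#' @slot pixelMapVNIR,pixelMapSWIR integer matrices of per-pixel class
#'   labels (0 = background).
#' @slot endmemberVNIR,endmemberSWIR class x bands matrices of true
#'   noiseless endmember spectra.
#' @export
setClass("GroundTruth",
  representation(sliceLabels = "integer", pixelMapVNIR = "matrix",
                 pixelMapSWIR = "matrix", endmemberVNIR = "matrix",
                 endmemberSWIR = "matrix"))
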