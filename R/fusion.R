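#' @include AllClasses.R
#' @include spa.R
NULL

#' Stratified calibration/prediction split
#'
#' Randomly splits samples per class, assigning `floor(trainFrac * n)`
#' of each class of size n to the calibration (training) set and the rest
#' to the prediction (test) set. The default 2/3 corresponds to a 2:1
#' split; class sizes (128, 48, 48) then give 149 calibration and 75
#' prediction samples for every seed.
#'
#' @param labels class labels (factor or coercible); each class needs at
#'   least 3 samples.
#' @param trainFrac calibration fraction per class, default 2/3.
#' @param seed integer seed for the per-class shuffles.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive, each sorted).
#' @export
stratifiedSplit <- function(labels, trainFrac = 2 / 3, seed = 1L) {
  y <- as.factor(labels)
  sizes <- table(y)
  if (any(sizes < 3L))
    stop("every class needs at least 3 samples; got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  .withSeed(seed, {
    train <- integer(0L)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      nTrain <- floor(trainFrac * length(idx))
      train <- c(train, sample(idx, nTrain))
    }
    list(train = sort(train),
         test = sort(setdiff(seq_along(y), train)))
  })
}

#' Column auto-scaling learned on calibration rows
#'
#' `autoscaleFit()` learns per-column mean and standard deviation on the
#' calibration matrix; `autoscaleApply()` centers and scales any matrix
#' with those statistics (so prediction rows never contribute to the
#' scaling). Columns with zero calibration sd are centered only (scale 1)
#' and flagged.
#'
#' @param XCal calibration samples x features matrix.
#' @return `autoscaleFit()`: list with `center`, `scale` and logical
#'   `constant` per column.
#' @rdname autoscale
#' @export
autoscaleFit <- function(XCal) {
  XCal <- as.matrix(XCal)
  center <- colMeans(XCal)
  scale <- apply(XCal, 2L, stats::sd)
  constant <- scale == 0 | !is.finite(scale)
  scale[constant] <- 1
  list(center = center, scale = scale, constant = constant)
}

#' @param X matrix to scale.
#' @param scaler result of [autoscaleFit()].
#' @return `autoscaleApply()`: the scaled matrix.
#' @rdname autoscale
#' @export
autoscaleApply <- function(X, scaler) {
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$center))
    stop("column count does not match scaler")
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

# Canonical fusion order of block tags.
.tagOrder <- c("VNIR_spec", "SWIR_spec", "VNIR_tex", "SWIR_tex")

#' Fuse feature blocks along one of the three fusion dimensions
#'
#' Low-level (feature-level) fusion: each block is autoscaled on its
#' calibration rows individually, then the blocks are concatenated
#' column-wise in the canonical tag order (VNIR_spec, SWIR_spec, VNIR_tex,
#' SWIR_tex). The three dimensions constrain which tags may be combined:
#' `"range"` fuses the two camera ranges of one modality, `"modality"`
#' fuses spectra with textures within one range, and `"all"` fuses all
#' four blocks.
#'
#' @param blocks list of [FeatureBlock-class] with aligned `sampleIds`.
#' @param dimension `"range"`, `"modality"` or `"all"`.
#' @param calRows integer indices of the calibration rows used to learn
#'   the per-column scaling (default: all rows).
#' @return A [FusedFeatures-class].
#' @export
fuseBlocks <- function(blocks, dimension = c("all", "range", "modality"),
                       calRows = NULL) {
  dimension <- match.arg(dimension)
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, is, logical(1L), "FeatureBlock")))
  tags <- vapply(blocks, function(b) b@blockTag, character(1L))

  ids <- blocks[[1L]]@sampleIds
  for (b in blocks[-1L])
    if (!identical(b@sampleIds, ids))
      stop("block sample ids are not aligned")
  if (is.null(calRows)) calRows <- seq_along(ids)

  ranges <- sub("_.*$", "", tags)
  mods <- sub("^.*_", "", tags)
  ok <- switch(dimension,
    range = length(unique(mods)) == 1L && length(unique(ranges)) == 2L,
    modality = length(unique(ranges)) == 1L && length(unique(mods)) == 2L,
    all = setequal(tags, .tagOrder))
  if (!ok)
    stop("block tags (", paste(tags, collapse = ", "),
         ") do not match fusion dimension '", dimension, "'")

  ord <- order(match(tags, .tagOrder))
  blocks <- blocks[ord]
  scalers <- lapply(blocks, function(b)
    autoscaleFit(b@values[calRows, , drop = FALSE]))
  scaled <- mapply(function(b, s) autoscaleApply(b@values, s),
                   blocks, scalers, SIMPLIFY = FALSE)
  vals <- do.call(cbind, scaled)
  labs <- unlist(lapply(blocks, function(b) b@columnLabels))
  colnames(vals) <- labs

  new("FusedFeatures", values = vals,
      provenance = vapply(blocks, function(b) b@blockTag, character(1L)),
      scaler = list(center = unlist(lapply(scalers, `[[`, "center")),
                    scale = unlist(lapply(scalers, `[[`, "scale")),
                    constant = unlist(lapply(scalers, `[[`, "constant"))),
      columnLabels = labs, sampleIds = ids)
}

#' Convert a SpectrumTable or TextureTable to a tagged FeatureBlock
#'
#' @param table a [SpectrumTable-class] or [TextureTable-class].
#' @param range `"VNIR"` or `"SWIR"`.
#' @return A [FeatureBlock-class] tagged `<range>_spec` or `<range>_tex`.
#' @export
asFeatureBlock <- function(table, range = c("VNIR", "SWIR")) {
  range <- match.arg(range)
  if (is(table, "SpectrumTable")) {
    featureBlock(table@values, paste0(range, "_spec"),
                 columnLabels = sprintf("spec_%g", table@wavelengths),
                 sampleIds = table@sampleIds)
  } else if (is(table, "TextureTable")) {
    featureBlock(table@values, paste0(range, "_tex"),
                 columnLabels = table@columnLabels,
                 sampleIds = table@sampleIds)
  } else stop("unsupported table class ", class(table))
}
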