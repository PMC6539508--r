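#' @include AllClasses.R
NULL

#' TextureTable: texture features per sample across effective wavelengths
#'
#' @slot values samples x (n_wavelengths x features_per_wavelength) matrix;
#'   20 features per wavelength for GLCM, 7 for GLRLM.
#' @slot columnLabels labels of the form `tex_<nm>_<feature>_<angle>`.
#' @slot method `"GLCM"` or `"GLRLM"`.
#' @slot sampleIds row identifiers.
#' @seealso [textureTable()]
#' @export
setClass("TextureTable",
  representation(values = "matrix", columnLabels = "character",
                 method = "character", sampleIds = "character"))

setValidity("TextureTable", function(object) {
  msgs <- character()
  if (!object@method %in% c("GLCM", "GLRLM"))
    msgs <- c(msgs, "method must be GLCM or GLRLM")
  if (length(object@columnLabels) != ncol(object@values))
    msgs <- c(msgs, "one column label per column required")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "texture values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
setMethod("featureValues", "TextureTable", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "TextureTable", function(x) x@sampleIds)

setMethod("show", "TextureTable", function(object) {
  cat(sprintf("TextureTable [%s]: %d samples x %d features\n",
              object@method, nrow(object@values), ncol(object@values)))
})

#' Quantize an ROI to integer gray levels
#'
#' Linear min-max mapping of in-mask intensities to levels 1..L
#' (`level = floor((x - min) / (max - min) * L) + 1`, clamped to L so the
#' maximum maps to L); pixels outside the mask are 0.
#'
#' @param bandImage numeric matrix of intensities.
#' @param mask logical matrix; `TRUE` = inside ROI.
#' @param L number of gray levels, default 16.
#' @return A [QuantizedImage-class].
#' @export
quantizeImage <- function(bandImage, mask, L = 16L) {
  stopifnot(identical(dim(bandImage), dim(mask)))
  L <- as.integer(L)
  v <- bandImage[mask]
  if (length(v) < 2L) stop("mask must contain at least 2 pixels")
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("constant ROI: texture quantization degenerate")
  lev <- pmin(L, 1L + as.integer(floor((v - lo) / (hi - lo) * L)))
  out <- matrix(0L, nrow(bandImage), ncol(bandImage))
  out[mask] <- lev
  new("QuantizedImage", levels = out, L = L)
}

# (drow, dcol) offsets of the four standard angles at distance d, in image
# coordinates where rows increase downwards: 0 deg = right, 45 deg =
# up-right, 90 deg = up, 135 deg = up-left.
.angleOffsets <- function(d = 1L) {
  list("0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

#' Gray-level co-occurrence (GLCM) features of one ROI image
#'
#' For each of the four angles (0, 45, 90, 135 degrees) at the given pixel
#' distance, the symmetric co-occurrence distribution P(i, j) is estimated
#' over all pixel pairs lying inside the mask, and five statistics are
#' derived: contrast \eqn{\sum (i-j)^2 P}, dissimilarity
#' \eqn{\sum |i-j| P}, homogeneity \eqn{\sum P / (1 + (i-j)^2)}, energy
#' \eqn{\sqrt{\sum P^2}}, and correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) P / (\sigma_i \sigma_j)} (defined as 0 when
#' \eqn{\sigma_i \sigma_j = 0}). The 20 values are returned feature-major,
#' angle-minor: contrast at the four angles, then dissimilarity, and so on.
#'
#' @param q a [QuantizedImage-class].
#' @param distance pixel offset distance, default 1.
#' @return Named numeric vector of length 20.
#' @export
glcmFeatures <- function(q, distance = 1L) {
  stopifnot(is(q, "QuantizedImage"))
  lev <- q@levels
  feats <- c("contrast", "dissimilarity", "homogeneity", "energy",
             "correlation")
  angles <- .angleOffsets(as.integer(distance))
  perAngle <- matrix(NA_real_, length(feats), length(angles),
                     dimnames = list(feats, names(angles)))
  for (a in names(angles)) {
    P <- .glcmMatrix(lev, q@L, angles[[a]])
    if (is.null(P))
      stop("no valid in-mask pixel pair at angle ", a, " degrees")
    perAngle[, a] <- .glcmStats(P)
  }
  out <- as.vector(t(perAngle))
  names(out) <- paste(rep(feats, each = length(angles)),
                      rep(names(angles), length(feats)), sep = "_")
  out
}

# Symmetric normalized co-occurrence matrix for one offset; NULL when no
# valid pair exists.
.glcmMatrix <- function(lev, L, off) {
  nr <- nrow(lev); nc <- ncol(lev)
  dr <- off[1L]; dc <- off[2L]
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(r0) || !length(c0)) return(NULL)
  A <- lev[r0, c0, drop = FALSE]
  B <- lev[r0 + dr, c0 + dc, drop = FALSE]
  ok <- A > 0L & B > 0L
  if (!any(ok)) return(NULL)
  i <- A[ok]; j <- B[ok]
  # symmetric: count each ordered pair both ways
  counts <- matrix(tabulate((c(i, j) - 1L) * L + c(j, i), L * L), L, L)
  counts / sum(counts)
}

.glcmStats <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi <- rowSums(P); pj <- colSums(P)
  mui <- sum(seq_len(L) * pi); muj <- sum(seq_len(L) * pj)
  sdi <- sqrt(sum((seq_len(L) - mui)^2 * pi))
  sdj <- sqrt(sum((seq_len(L) - muj)^2 * pj))
  corr <- if (sdi * sdj == 0) 0 else
    sum((i - mui) * (j - muj) * P) / (sdi * sdj)
  c(contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sqrt(sum(P^2)),
    correlation = corr)
}

#' Gray-level run-length (GLRLM) features of one ROI image
#'
#' For each of the four angles the run-length matrix p(i, j) counts the
#' maximal in-mask runs of gray level i and length j (runs are broken by
#' mask boundaries). With \eqn{N_r = \sum p} runs and \eqn{N_p} in-mask
#' pixels, the seven measures are: short run emphasis
#' \eqn{\sum p/j^2 / N_r}, long run emphasis \eqn{\sum p j^2 / N_r},
#' gray-level non-uniformity \eqn{\sum_i (\sum_j p)^2 / N_r}, run
#' percentage \eqn{N_r / N_p}, run-length non-uniformity
#' \eqn{\sum_j (\sum_i p)^2 / N_r}, and low/high gray-level run emphasis
#' \eqn{\sum p/i^2 / N_r}, \eqn{\sum p i^2 / N_r} (levels indexed from 1).
#' The returned values are unweighted means over the four angles.
#'
#' @param q a [QuantizedImage-class].
#' @param angles angle names to use (default all four).
#' @return Named numeric vector of length 7 (SRE, LRE, GLN, RP, RLN,
#'   LGLRE, HGLRE).
#' @export
glrlmFeatures <- function(q, angles = c("0", "45", "90", "135")) {
  stopifnot(is(q, "QuantizedImage"))
  if (!any(q@levels > 0L)) stop("empty mask")
  proto <- c(SRE = 0, LRE = 0, GLN = 0, RP = 0, RLN = 0, LGLRE = 0,
             HGLRE = 0)
  perAngle <- vapply(angles, function(a) {
    runs <- .runLengths(q@levels, a)
    if (is.null(runs) || !nrow(runs))
      stop("no in-mask run at angle ", a, " degrees")
    .glrlmStats(runs)
  }, proto)
  rowMeans(perAngle)
}

# Maximal runs along one angle: data.frame(level, length), one row per run.
.runLengths <- function(lev, angle) {
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(angle,
    "0" = lapply(seq_len(nr), function(r) lev[r, ]),
    "90" = lapply(seq_len(nc), function(c) lev[, c]),
    "45" = lapply(seq_len(nr + nc - 1L), function(k) {
      # anti-diagonals r + c = k + 1
      r <- max(1L, k + 1L - nc):min(nr, k)
      lev[cbind(r, k + 1L - r)]
    }),
    "135" = lapply(seq_len(nr + nc - 1L), function(k) {
      # diagonals r - c = k - nc
      r <- max(1L, k - nc + 1L):min(nr, k)
      lev[cbind(r, r - k + nc)]
    }),
    stop("unknown angle ", angle))
  runs <- lapply(lines, function(v) {
    e <- rle(as.integer(v))
    keep <- e$values > 0L
    cbind(e$values[keep], e$lengths[keep])
  })
  do.call(rbind, runs)
}

.glrlmStats <- function(runs) {
  if (is.null(runs) || !nrow(runs)) stop("no in-mask run at this angle")
  i <- runs[, 1L]; j <- runs[, 2L]
  Nr <- nrow(runs)
  Np <- sum(j)
  gl <- tapply(rep(1L, Nr), i, sum)          # runs per gray level
  rl <- tapply(rep(1L, Nr), j, sum)          # runs per run length
  c(SRE = sum(1 / j^2) / Nr,
    LRE = sum(j^2) / Nr,
    GLN = sum(gl^2) / Nr,
    RP = Nr / Np,
    RLN = sum(rl^2) / Nr,
    LGLRE = sum(1 / i^2) / Nr,
    HGLRE = sum(i^2) / Nr)
}

#' Texture features of all ROIs at the effective wavelengths
#'
#' For every ROI and every selected wavelength, the calibrated band image
#' is quantized over the ROI mask and the GLCM (20 values) or GLRLM
#' (7 values) statistics are extracted; features are concatenated per
#' sample in wavelength-major order.
#'
#' @param cube a calibrated [HyperCube-class].
#' @param rois list of [SliceROI-class].
#' @param selected a [SelectedWavelengths-class], or an integer vector of
#'   band indices.
#' @param method `"GLCM"` or `"GLRLM"`.
#' @param L gray-level count for quantization, default 16.
#' @param distance GLCM pixel distance, default 1.
#' @return A [TextureTable-class] with `20 * n_wavelengths` (GLCM) or
#'   `7 * n_wavelengths` (GLRLM) columns.
#' @export
textureTable <- function(cube, rois, selected, method = c("GLCM", "GLRLM"),
                         L = 16L, distance = 1L) {
  method <- match.arg(method)
  stopifnot(is(cube, "HyperCube"))
  bands <- if (is(selected, "SelectedWavelengths")) selected@bandIndices
           else as.integer(selected)
  if (any(bands < 1L) || any(bands > nBands(cube)))
    stop("selected band index outside cube")
  wl <- cube@wavelengths[bands]

  rows <- lapply(rois, function(roi) {
    unlist(lapply(seq_along(bands), function(k) {
      v <- tryCatch({
        qi <- quantizeImage(cube@data[, , bands[k]], roi@mask, L = L)
        if (method == "GLCM") glcmFeatures(qi, distance = distance)
        else glrlmFeatures(qi)
      }, error = function(e)
        stop("ROI ", roi@roiId, " at ", wl[k], " nm: ",
             conditionMessage(e), call. = FALSE))
      names(v) <- sprintf("tex_%g_%s", wl[k], names(v))
      v
    }))
  })
  vals <- do.call(rbind, rows)
  new("TextureTable", values = vals, columnLabels = colnames(vals),
      method = method,
      sampleIds = paste0("roi", vapply(rois, roiId, integer(1L))))
}
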