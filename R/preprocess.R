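#' @include AllClasses.R
NULL

# All preprocessing operators act rowwise (per spectrum) on a
# SpectrumTable or a bare samples x bands matrix and never change shape.

.asValues <- function(table) {
  if (is(table, "SpectrumTable")) table@values else as.matrix(table)
}

.rewrap <- function(table, values) {
  if (is(table, "SpectrumTable")) {
    out <- table
    out@values <- values
    validObject(out)
    out
  } else values
}

#' Standard normal variate (SNV) transform
#'
#' Z-scores every spectrum: subtracts its mean and divides by its
#' population standard deviation (divisor n). Removes per-sample
#' multiplicative and additive scatter effects.
#'
#' @param table a [SpectrumTable-class] or samples x bands matrix.
#' @return Object of the same kind with each row at mean 0, sd 1.
#' @export
snv <- function(table) {
  X <- .asValues(table)
  mu <- rowMeans(X)
  sdp <- sqrt(rowMeans((X - mu)^2))
  bad <- which(sdp == 0)
  if (length(bad)) {
    ids <- if (is(table, "SpectrumTable")) table@sampleIds[bad] else bad
    stop("zero-variance spectrum: ", paste(ids, collapse = ", "))
  }
  .rewrap(table, (X - mu) / sdp)
}

#' Multiplicative scatter correction (MSC)
#'
#' `mscFit()` learns the reference spectrum (the mean spectrum of the
#' calibration set); `mscApply()` regresses each spectrum x on the
#' reference by ordinary least squares, `x ~ a + b * reference`, and
#' returns `(x - a) / b`, exactly undoing a per-sample affine scatter
#' distortion. The calibration-set reference is reused for prediction
#' samples so no test statistics leak into the correction.
#'
#' @param calibrationTable calibration [SpectrumTable-class] or matrix.
#' @return `mscFit()`: the reference spectrum (numeric vector).
#' @rdname msc
#' @export
mscFit <- function(calibrationTable) {
  X <- .asValues(calibrationTable)
  ref <- colMeans(X)
  if (stats::var(ref) == 0) stop("reference spectrum has zero variance")
  ref
}

#' @param table table to correct.
#' @param reference reference spectrum from [mscFit()].
#' @return `mscApply()`: the corrected table.
#' @rdname msc
#' @export
mscApply <- function(table, reference) {
  X <- .asValues(table)
  if (ncol(X) != length(reference))
    stop("reference length does not match band count")
  refC <- reference - mean(reference)
  denom <- sum(refC^2)
  if (denom < 1e-24) stop("reference spectrum has zero variance")
  # OLS slope of x on ref: b = <x - mean(x), ref - mean(ref)> / ||ref - mean(ref)||^2
  b <- as.vector((X - rowMeans(X)) %*% refC) / denom
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < 1e-12))
    stop("degenerate MSC slope for sample(s): ",
         paste(which(abs(b) < 1e-12), collapse = ", "))
  .rewrap(table, (X - a) / b)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of each spectrum; boundary
#' points are handled by evaluating the window polynomial fitted at the
#' ends, so polynomials up to `polyorder` are reproduced exactly
#' everywhere.
#'
#' @param table a [SpectrumTable-class] or matrix.
#' @param window odd window length in points (9, 13, 17 or 21 are the
#'   usual choices).
#' @param polyorder polynomial order, default 3.
#' @return The smoothed table.
#' @export
sgSmooth <- function(table, window = 17L, polyorder = 3L) {
  .sgApply(table, window, polyorder, deriv = 0L)
}

#' Savitzky-Golay derivative
#'
#' First or second derivative with respect to band index, computed with a
#' single Savitzky-Golay derivative filter (smoothing and differentiation
#' in one local polynomial fit; the default 17-point window does the
#' smoothing). Units are per band-index step; set `perNm = TRUE` to divide
#' by the local wavelength step instead.
#'
#' @param table a [SpectrumTable-class] or matrix.
#' @param order derivative order, 1 or 2.
#' @param window odd window length, default 17.
#' @param polyorder polynomial order, default 3.
#' @param perNm rescale to per-nm units using the median wavelength step
#'   (requires a [SpectrumTable-class]).
#' @return The differentiated table.
#' @export
sgDerivative <- function(table, order, window = 17L, polyorder = 3L,
                         perNm = FALSE) {
  if (!order %in% c(1L, 2L)) stop("derivative order must be 1 or 2")
  out <- .sgApply(table, window, polyorder, deriv = as.integer(order))
  if (perNm) {
    if (!is(table, "SpectrumTable"))
      stop("perNm rescaling needs a SpectrumTable with wavelengths")
    h <- stats::median(diff(table@wavelengths))
    out@values <- out@values / h^order
  }
  out
}

.sgApply <- function(table, window, polyorder, deriv) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  X <- .asValues(table)
  if (ncol(X) < window)
    stop("need at least ", window, " bands for a ", window, "-point window")
  out <- t(apply(X, 1L, function(x)
    signal::sgolayfilt(x, p = polyorder, n = window, m = deriv)))
  # sgolayfilt's m-th derivative carries the analytic m! factor already
  .rewrap(table, out)
}

#' Apply a preprocessing recipe
#'
#' Dispatches a [PreprocessSpec-class] over a table. For MSC the reference
#' must be learned on the calibration rows: pass `reference`, or the
#' calibration table via `calibrationTable` (defaults to `table` itself,
#' appropriate when preprocessing the calibration set).
#'
#' @param table a [SpectrumTable-class] or matrix.
#' @param spec a [PreprocessSpec-class].
#' @param reference optional MSC reference spectrum.
#' @param calibrationTable optional table from which to learn the MSC
#'   reference.
#' @return The preprocessed table.
#' @export
preprocessSpectra <- function(table, spec = preprocessSpec(),
                              reference = NULL, calibrationTable = NULL) {
  stopifnot(is(spec, "PreprocessSpec"))
  switch(spec@method,
    none = table,
    snv = snv(table),
    msc = {
      if (is.null(reference))
        reference <- mscFit(if (is.null(calibrationTable)) table
                            else calibrationTable)
      mscApply(table, reference)
    },
    sg_smooth = sgSmooth(table, spec@sgWindow, spec@sgPolyorder),
    d1 = sgDerivative(table, 1L, spec@sgWindow, spec@sgPolyorder),
    d2 = sgDerivative(table, 2L, spec@sgWindow, spec@sgPolyorder))
}
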