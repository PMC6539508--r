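#' @include AllClasses.R
NULL

#' Successive projections chain from one start band
#'
#' The forward pass of the successive projections algorithm (SPA): step 1
#' picks the start column; every later step projects all unchosen columns
#' onto the orthogonal complement of the span of the chosen columns and
#' picks the column with the largest projected Euclidean norm (ties broken
#' by lowest band index). The chain stops at `maxLen` or when the largest
#' projected norm falls below `1e-12` (column space exhausted).
#'
#' @param X samples x bands matrix, column-autoscaled.
#' @param startIndex 1-based index of the seed column.
#' @param maxLen maximum chain length, at most `min(nrow(X) - 1, ncol(X))`.
#' @return An [SpaChain-class].
#' @seealso [spaSelect()]
#' @export
spaChain <- function(X, startIndex, maxLen) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  maxLen <- as.integer(maxLen)
  if (maxLen > min(n - 1L, p))
    stop("maxLen must not exceed min(n_samples - 1, bands)")
  stopifnot(startIndex >= 1L, startIndex <= p)

  R <- X                       # residuals after projecting out chosen span
  chosen <- integer(0L)
  norms <- numeric(0L)
  nextIdx <- as.integer(startIndex)
  repeat {
    v <- R[, nextIdx]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break      # rank exhausted
    chosen <- c(chosen, nextIdx)
    norms <- c(norms, nv)
    if (length(chosen) >= maxLen) break
    u <- v / nv
    R <- R - u %*% crossprod(u, R)   # deflate the chosen direction
    R[, chosen] <- 0
    colNorms <- sqrt(colSums(R^2))
    if (max(colNorms) < 1e-12) break
    nextIdx <- which.max(colNorms)   # which.max: first (lowest) index wins
  }
  new("SpaChain", startIndex = as.integer(startIndex),
      indices = chosen, projectedNorms = norms)
}

#' SPA effective-wavelength selection
#'
#' Phase 1 builds one projection chain per start band ([spaChain()]); phase
#' 2 scores every chain prefix with length in `[nMin, nMax]` by stratified
#' `folds`-fold cross-validated misclassification of a least-squares
#' one-hot linear classifier restricted to those bands, and returns the
#' subset with the smallest CV error. Ties favor fewer bands, then the
#' lower start index. The only randomness is the fold assignment, driven
#' by `seed`.
#'
#' @param X samples x bands matrix of calibration spectra (autoscaled
#'   internally on its own statistics).
#' @param y class labels (factor or coercible).
#' @param nMin,nMax candidate subset sizes; `nMax` capped at
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param folds number of CV folds, default 5.
#' @param seed integer seed for the fold assignment.
#' @param wavelengths optional wavelength vector for labelling the result.
#' @return A [SelectedWavelengths-class].
#' @export
spaSelect <- function(X, y, nMin = 2L, nMax = 30L, folds = 5L, seed = 1L,
                      wavelengths = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  nMax <- min(as.integer(nMax), n - 1L, p)
  nMin <- as.integer(nMin)
  if (nMin < 1L || nMin > nMax)
    stop("need 1 <= nMin <= nMax (achievable nMax = ", nMax, ")")

  Xs <- .autoscaleCols(X)
  foldId <- .stratifiedFolds(y, folds, seed)

  best <- NULL   # list(err, len, start, subset)
  scored <- new.env(parent = emptyenv())   # memoize identical subsets
  for (start in seq_len(p)) {
    chain <- spaChain(Xs, start, nMax)
    idx <- chain@indices
    if (length(idx) < nMin) next
    for (len in nMin:length(idx)) {
      subset <- sort(idx[seq_len(len)])
      key <- paste(subset, collapse = ",")
      err <- scored[[key]]
      if (is.null(err)) {
        err <- .cvErrorLinear(Xs[, subset, drop = FALSE], y, foldId)
        scored[[key]] <- err
      }
      if (is.null(best) || err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 &&
           (len < best$len || (len == best$len && start < best$start)))) {
        best <- list(err = err, len = len, start = start, subset = subset)
      }
    }
  }
  if (is.null(best)) stop("no chain reached length nMin = ", nMin)

  wl <- if (is.null(wavelengths)) as.numeric(best$subset)
        else wavelengths[best$subset]
  new("SelectedWavelengths",
      bandIndices = as.integer(best$subset), wavelengthsNm = as.numeric(wl),
      cvError = best$err,
      chainProvenance = as.integer(c(best$start, best$len)))
}

# Column autoscale helper used by SPA (population of the given matrix);
# zero-sd columns are centered only.
.autoscaleCols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sd, "/")
}

# Stratified fold ids: within each class, shuffle and deal round-robin.
# Runs under its own seed; the caller's RNG state is untouched.
.stratifiedFolds <- function(y, folds, seed) {
  .withSeed(seed, {
    foldId <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      foldId[idx] <- rep_len(seq_len(folds), length(idx))
    }
    foldId
  })
}

# Misclassification rate of a least-squares one-hot linear classifier
# (intercept + selected columns, argmax decision) under the given folds.
.cvErrorLinear <- function(Xs, y, foldId) {
  Y <- .oneHot(y)
  nErr <- 0L
  for (f in sort(unique(foldId))) {
    tr <- foldId != f
    A <- cbind(1, Xs[tr, , drop = FALSE])
    B <- tryCatch(qr.coef(qr(A), Y[tr, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(B)) { nErr <- nErr + sum(!tr); next }
    B[is.na(B)] <- 0
    pred <- cbind(1, Xs[!tr, , drop = FALSE]) %*% B
    nErr <- nErr + sum(max.col(pred, ties.method = "first") !=
                         as.integer(y[!tr]))
  }
  nErr / length(y)
}

.oneHot <- function(y) {
  y <- as.factor(y)
  Y <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
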