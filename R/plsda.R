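#' @include AllClasses.R
#' @include spa.R
NULL

#' PLS-DA: partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS2 regression of the centered one-hot class indicator matrix
#' on the feature matrix with the NIPALS algorithm, extracting `nLatent`
#' latent variables. Prediction takes the argmax of the continuous class
#' scores; the scores themselves feed ROC analysis. The feature matrix is
#' expected to be auto-scaled already (see [autoscaleFit()]); the fit only
#' centers it.
#'
#' With `nLatent` equal to the rank of the centered feature matrix,
#' predictions coincide with least-squares one-hot regression.
#'
#' @param X samples x features matrix (auto-scaled).
#' @param labels class labels (factor or coercible).
#' @param nLatent number of latent variables, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param maxIter,tol NIPALS iteration cap and convergence tolerance; more
#'   than `maxIter` inner iterations raises a numerical error.
#' @return An object of class `"plsda"`: list with the projection weights
#'   `W`, loadings `P`, `Q`, regression coefficients `B`, the centers and
#'   class levels.
#' @seealso [plsdaPredict()], [plsdaSelectLatent()]
#' @export
plsdaFit <- function(X, labels, nLatent, maxIter = 500L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  n <- nrow(X); p <- ncol(X)
  nLatent <- as.integer(nLatent)
  if (nLatent < 1L || nLatent > min(n - 1L, p))
    stop("nLatent must lie in 1..min(n - 1, features)")

  Y <- .oneHot(y)
  xCenter <- colMeans(X)
  yCenter <- colMeans(Y)
  E <- sweep(X, 2L, xCenter)
  F <- sweep(Y, 2L, yCenter)

  W <- matrix(0, p, nLatent)
  P <- matrix(0, p, nLatent)
  Q <- matrix(0, ncol(Y), nLatent)
  Tm <- matrix(0, n, nLatent)
  nUsed <- 0L
  for (a in seq_len(nLatent)) {
    if (sum(E^2) < 1e-24 || sum(F^2) < 1e-24) break  # nothing left to model
    u <- F[, which.max(apply(F, 2L, stats::var))]
    tOld <- rep(Inf, n)
    for (it in seq_len(maxIter + 1L)) {
      if (it > maxIter)
        stop("NIPALS failed to converge in ", maxIter, " iterations")
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) break
      w <- w / nw
      tt <- E %*% w
      qv <- crossprod(F, tt) / sum(tt^2)
      u <- F %*% qv / sum(qv^2)
      if (sqrt(sum((tt - tOld)^2)) < tol * sqrt(sum(tt^2))) break
      tOld <- tt
    }
    pv <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(pv)
    F <- F - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    nUsed <- a
  }
  if (nUsed == 0L) stop("degenerate input: no latent variable extractable")
  W <- W[, seq_len(nUsed), drop = FALSE]
  P <- P[, seq_len(nUsed), drop = FALSE]
  Q <- Q[, seq_len(nUsed), drop = FALSE]
  Tm <- Tm[, seq_len(nUsed), drop = FALSE]
  # coefficients on centered data: B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(W = W, P = P, Q = Q, B = B, scoresTrain = Tm,
                 xCenter = xCenter, yCenter = yCenter,
                 levels = levels(y), nLatent = nUsed),
            class = "plsda")
}

#' Predict classes and continuous scores from a PLS-DA model
#'
#' @param model a `"plsda"` fit from [plsdaFit()].
#' @param X new samples x features matrix on the same feature grid and
#'   scaling as the training data.
#' @return List with `labels` (factor) and `scores` (samples x classes
#'   matrix of continuous class responses).
#' @export
plsdaPredict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$xCenter))
    stop("feature count does not match the fitted model")
  scores <- sweep(X, 2L, model$xCenter) %*% model$B
  scores <- sweep(scores, 2L, model$yCenter, "+")
  colnames(scores) <- model$levels
  labels <- factor(model$levels[max.col(scores, ties.method = "first")],
                   levels = model$levels)
  list(labels = labels, scores = scores)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA (NIPALS): %d latent variables, %d features, classes: %s\n",
              x$nLatent, length(x$xCenter), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Choose the PLS-DA latent-variable count by repeated cross-validation
#'
#' Scores each candidate count by stratified repeated k-fold CV accuracy
#' and returns the candidate with the highest mean accuracy (ties: fewer
#' latent variables).
#'
#' @param X auto-scaled samples x features matrix.
#' @param labels class labels.
#' @param candidates latent counts to try, default 1..10.
#' @param times,folds CV repeats and folds (default 10 x 5).
#' @param seed integer seed.
#' @return List with `nLatent` (the winner) and `cvAccuracy` (named mean
#'   accuracy per candidate).
#' @export
plsdaSelectLatent <- function(X, labels, candidates = 1:10, times = 10L,
                              folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(labels)
  cap <- min(nrow(X) - ceiling(nrow(X) / folds) - 1L, ncol(X))
  candidates <- candidates[candidates <= cap]
  if (!length(candidates)) stop("no feasible latent count")
  acc <- vapply(candidates, function(a) {
    cv <- crossValidate(list(type = "plsda", nLatent = a), X, y,
                        times = times, folds = folds, seed = seed)
    cv$mean
  }, numeric(1L))
  names(acc) <- candidates
  list(nLatent = candidates[which.max(acc)], cvAccuracy = acc)
}
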