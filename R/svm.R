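#' @include AllClasses.R
#' @include spa.R
NULL

#' RBF-kernel SVM with grid-searched hyperparameters
#'
#' Trains a soft-margin radial-basis-function SVM (one-vs-one multiclass,
#' libsvm via \pkg{e1071}) on auto-scaled features. The penalty parameter
#' C and kernel coefficient g are chosen on the decade grid
#' `{0.001, 0.01, 0.1, 1, 10}^2` by stratified cross-validated accuracy;
#' ties favor the smaller C, then the smaller g.
#'
#' @param X auto-scaled samples x features matrix.
#' @param labels class labels; at least two classes.
#' @param CGrid,gGrid candidate values for C and g.
#' @param folds CV folds for the grid search, default 5.
#' @param seed integer seed for the fold assignment.
#' @return An `e1071::svm` fit with the chosen `C`/`gamma` recorded in
#'   attributes `"C"` and `"g"` and the grid accuracies in `"gridAccuracy"`.
#' @export
svmTrain <- function(X, labels, CGrid = c(0.001, 0.01, 0.1, 1, 10),
                     gGrid = c(0.001, 0.01, 0.1, 1, 10), folds = 5L,
                     seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("degenerate single-class input")
  foldId <- .stratifiedFolds(y, folds, seed)

  grid <- expand.grid(C = sort(CGrid), g = sort(gGrid))
  accs <- vapply(seq_len(nrow(grid)), function(k) {
    hits <- 0L
    for (f in sort(unique(foldId))) {
      tr <- foldId != f
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$C[k], gamma = grid$g[k], scale = FALSE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1L))

  # best accuracy; ties -> smaller C, then smaller g (grid is sorted by g
  # within C only after reordering)
  ord <- order(-accs, grid$C, grid$g)
  best <- ord[1L]
  fit <- e1071::svm(X, y, kernel = "radial", cost = grid$C[best],
                    gamma = grid$g[best], scale = FALSE)
  attr(fit, "C") <- grid$C[best]
  attr(fit, "g") <- grid$g[best]
  attr(fit, "gridAccuracy") <- cbind(grid, accuracy = accs)
  fit
}

#' Predict classes and vote-based scores from an SVM fit
#'
#' One-vs-one vote fractions serve as the per-class continuous scores
#' (coarser than PLS-DA responses but usable for ROC ranking).
#'
#' @param model fit from [svmTrain()].
#' @param X samples x features matrix.
#' @return List with `labels` and `scores` (vote fractions per class).
#' @export
svmPredict <- function(model, X) {
  X <- as.matrix(X)
  pred <- stats::predict(model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lev <- model$levels
  votes <- matrix(0, nrow(X), length(lev), dimnames = list(NULL, lev))
  for (cmp in colnames(dv)) {
    pair <- strsplit(cmp, "/", fixed = TRUE)[[1L]]
    win <- ifelse(dv[, cmp] > 0, pair[1L], pair[2L])
    votes[cbind(seq_len(nrow(X)), match(win, lev))] <-
      votes[cbind(seq_len(nrow(X)), match(win, lev))] + 1
  }
  list(labels = factor(as.character(pred), levels = lev),
       scores = votes / max(1L, ncol(dv)))
}
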