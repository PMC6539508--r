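#' @include AllClasses.R
#' @include plsda.R
#' @include svm.R
#' @include fusion.R
NULL

# Fit a model described by modelSpec on (X, y); returns a closure that
# predicts (labels, scores) on new rows. modelSpec: list(type = "plsda",
# nLatent = k) or list(type = "svm", CGrid = ..., gGrid = ...).
.fitModel <- function(modelSpec, X, y, seed = 1L) {
  switch(modelSpec$type,
    plsda = {
      nl <- min(modelSpec$nLatent %||% 5L, nrow(X) - 1L, ncol(X))
      # near-noise folds (eigenvalue near-ties) converge slowly; the
      # pipeline allows NIPALS a generous iteration budget
      fit <- plsdaFit(X, y, nLatent = nl,
                      maxIter = modelSpec$maxIter %||% 5000L)
      function(Xnew) plsdaPredict(fit, Xnew)
    },
    svm = {
      fit <- svmTrain(X, y,
                      CGrid = modelSpec$CGrid %||% c(0.001, 0.01, 0.1, 1, 10),
                      gGrid = modelSpec$gGrid %||% c(0.001, 0.01, 0.1, 1, 10),
                      seed = seed)
      function(Xnew) svmPredict(fit, Xnew)
    },
    stop("unknown model type ", modelSpec$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Repeated stratified cross-validation
#'
#' Ten-time five-fold (by default) stratified cross-validation of a model
#' specification. Fold assignments are re-randomized on every repeat from
#' `seed`. All statistics that depend on the training rows — the
#' per-column auto-scaling, the optional per-fold column selector, and the
#' model itself — are refit inside each training fold, so no test-row
#' information leaks into the fit.
#'
#' @param modelSpec list describing the model: `list(type = "plsda",
#'   nLatent = k)` or `list(type = "svm", CGrid, gGrid)`.
#' @param X samples x features matrix of unscaled features, or a list of
#'   [FeatureBlock-class] objects to be fused per fold (see `dimension`).
#' @param y class labels.
#' @param times,folds repeats and folds, default 10 x 5.
#' @param seed integer seed.
#' @param dimension fusion dimension when `X` is a block list.
#' @param selector optional `function(Xtrain, ytrain) -> column indices`
#'   refit inside each fold (e.g. an SPA wrapper).
#' @return List with `mean` and `sd` of the per-fold accuracies, `nFolds`,
#'   and the full `foldAccuracy` vector.
#' @export
crossValidate <- function(modelSpec, X, y, times = 10L, folds = 5L,
                          seed = 1L, dimension = "all", selector = NULL) {
  y <- as.factor(y)
  blocks <- NULL
  if (is.list(X) && !is.data.frame(X)) {
    blocks <- X
    n <- nrow(blocks[[1L]]@values)
  } else {
    X <- as.matrix(X)
    n <- nrow(X)
  }
  stopifnot(length(y) == n)

  accs <- numeric(0L)
  for (rep in seq_len(times)) {
    foldId <- .stratifiedFolds(y, folds, seed + 7919L * (rep - 1L))
    for (f in sort(unique(foldId))) {
      tr <- which(foldId != f)
      te <- which(foldId == f)
      if (!is.null(blocks)) {
        fused <- fuseBlocks(blocks, dimension = dimension, calRows = tr)
        Xs <- fused@values
      } else {
        scaler <- autoscaleFit(X[tr, , drop = FALSE])
        Xs <- autoscaleApply(X, scaler)
      }
      if (!is.null(selector)) {
        keep <- selector(Xs[tr, , drop = FALSE], y[tr])
        Xs <- Xs[, keep, drop = FALSE]
      }
      predict <- .fitModel(modelSpec, Xs[tr, , drop = FALSE], y[tr],
                           seed = seed)
      pred <- predict(Xs[te, , drop = FALSE])$labels
      accs <- c(accs, mean(pred == y[te]))
    }
  }
  list(mean = mean(accs), sd = stats::sd(accs),
       nFolds = length(accs), foldAccuracy = accs)
}

#' One-vs-rest ROC curves and AUC from continuous class scores
#'
#' For each class, ranks all samples by that class's score, builds the ROC
#' curve (true-positive rate against false-positive rate, one step per
#' distinct score value) and integrates it by the trapezoidal rule. The
#' macro AUC is the unweighted mean over classes. AUC is a rank statistic:
#' any strictly increasing transform of the scores leaves it unchanged.
#'
#' @param scores samples x classes matrix of continuous scores with class
#'   column names (as from [plsdaPredict()]).
#' @param labels true class labels.
#' @return List with `perClass` (named numeric) and `macro` (scalar).
#' @export
rocAuc <- function(scores, labels) {
  y <- as.factor(labels)
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes)) classes <- levels(y)
  per <- vapply(seq_along(classes), function(k) {
    .binaryAuc(scores[, k], y == classes[k])
  }, numeric(1L))
  names(per) <- classes
  list(perClass = per, macro = mean(per))
}

# Trapezoidal AUC of the one-vs-rest ROC curve; ties grouped by distinct
# score value.
.binaryAuc <- function(score, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: a class has no positive or no negative sample")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- positive[ord]
  grp <- cumsum(!duplicated(s))          # ties share a threshold
  tpSteps <- tapply(p, grp, sum)
  fpSteps <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tpSteps) / nPos)
  fpr <- c(0, cumsum(fpSteps) / nNeg)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' ROC curve points for one class
#'
#' @param score numeric score vector for the class of interest.
#' @param positive logical vector, `TRUE` for samples of that class.
#' @return data.frame with `fpr` and `tpr` columns (including the (0,0)
#'   and (1,1) endpoints), suitable for CSV export or plotting.
#' @export
rocCurve <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tpr <- c(0, cumsum(tapply(p, grp, sum)) / sum(positive))
  fpr <- c(0, cumsum(tapply(!p, grp, sum)) / sum(!positive))
  data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr))
}

#' Fit, predict and summarize one pipeline configuration
#'
#' Fits the model on the calibration rows, evaluates calibration and
#' prediction accuracy, the prediction-set confusion matrix and
#' one-vs-rest ROC/AUC, and (optionally) attaches a repeated-CV summary
#' computed on the calibration rows only.
#'
#' @param modelSpec model description, see [crossValidate()].
#' @param XCal,yCal auto-scaled calibration features and labels.
#' @param XPre,yPre prediction (test) features on the same scaling, and
#'   labels.
#' @param cv logical; also run the repeated CV on the calibration rows.
#' @param times,folds,seed CV parameters.
#' @return A [ModelReport-class].
#' @export
evaluateModel <- function(modelSpec, XCal, yCal, XPre, yPre, cv = FALSE,
                          times = 10L, folds = 5L, seed = 1L) {
  yCal <- as.factor(yCal)
  yPre <- factor(yPre, levels = levels(yCal))
  predict <- .fitModel(modelSpec, XCal, yCal, seed = seed)

  predCal <- predict(XCal)
  predPre <- predict(XPre)
  confusion <- table(truth = yPre, predicted = predPre$labels)
  auc <- rocAuc(predPre$scores, yPre)

  cvSummary <- if (cv)
    crossValidate(modelSpec, XCal, yCal, times = times, folds = folds,
                  seed = seed)[c("mean", "sd", "nFolds")]
  else list()

  new("ModelReport",
      accuracyCal = 100 * mean(predCal$labels == yCal),
      accuracyPre = 100 * mean(predPre$labels == yPre),
      confusion = unclass(confusion),
      aucPerClass = auc$perClass, aucMacro = auc$macro,
      modelSpec = modelSpec, cvSummary = cvSummary)
}

#' Serialize a ModelReport to JSON
#'
#' @param report a [ModelReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModelReport <- function(report, path) {
  jsonlite::write_json(list(
    model = report@modelSpec,
    accuracy_cal = report@accuracyCal,
    accuracy_pre = report@accuracyPre,
    confusion = as.data.frame.matrix(report@confusion),
    auc_per_class = as.list(report@aucPerClass),
    auc_macro = report@aucMacro,
    cv = report@cvSummary
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
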