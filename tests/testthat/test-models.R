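twoClusters <- function(n = 20, sep = 4, seed = 81, p = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), n / 2),
             matrix(rnorm(n / 2 * p, mean = sep), n / 2))
  list(X = scale(X), y = factor(rep(c("a", "b"), each = n / 2)))
}

test_that("PLS-DA separates linearly separable clusters with one LV", {
  d <- twoClusters()
  fit <- plsdaFit(d$X, d$y, nLatent = 1)
  pred <- plsdaPredict(fit, d$X)
  expect_equal(mean(pred$labels == d$y), 1)
  expect_equal(colnames(pred$scores), levels(d$y))
})

test_that("a single feature equal to the class margin predicts perfectly", {
  y <- factor(rep(c("a", "b"), each = 8))
  X <- matrix(ifelse(y == "a", 1, -1) + rnorm(16, 0, 1e-6), ncol = 1)
  fit <- plsdaFit(X, y, nLatent = 1)
  expect_equal(mean(plsdaPredict(fit, X)$labels == y), 1)
})

test_that("first latent weight matches the dominant eigenvector oracle", {
  set.seed(82)
  X <- scale(matrix(rnorm(10 * 4), 10, 4))
  y <- factor(sample(c("a", "b", "c"), 10, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3)))
  fit <- plsdaFit(X, y, nLatent = 2)
  Y <- model.matrix(~ y - 1)
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  M <- crossprod(Xc, Yc) %*% crossprod(Yc, Xc)
  w1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(fit$W[, 1] * w1)), 1, tolerance = 1e-6)
})

test_that("full-rank PLS-DA reproduces least-squares one-hot regression", {
  set.seed(83)
  X <- scale(matrix(rnorm(20 * 5), 20, 5))
  y <- factor(rep(c("a", "b", "c"), length.out = 20))
  fit <- plsdaFit(X, y, nLatent = 5)
  scores <- plsdaPredict(fit, X)$scores

  Y <- model.matrix(~ y - 1)
  ls <- cbind(1, X) %*% qr.coef(qr(cbind(1, X)), Y)
  expect_equal(unname(scores), unname(ls), tolerance = 1e-6)
})

test_that("PLS-DA validates its inputs", {
  d <- twoClusters()
  expect_error(plsdaFit(d$X, d$y, nLatent = 0), "nLatent")
  expect_error(plsdaFit(d$X, d$y, nLatent = 25), "nLatent")
  expect_error(plsdaFit(d$X, factor(rep("a", 20)), 1), "two classes")
  fit <- plsdaFit(d$X, d$y, 2)
  expect_error(plsdaPredict(fit, d$X[, 1:2]), "feature count")
})

test_that("model reports are invariant to feature permutation", {
  set.seed(84)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- factor(rep(c("a", "b", "c"), length.out = 30))
  perm <- sample(6)
  r1 <- evaluateModel(list(type = "plsda", nLatent = 3),
                      scale(X)[1:21, ], y[1:21],
                      scale(X)[22:30, ], y[22:30])
  r2 <- evaluateModel(list(type = "plsda", nLatent = 3),
                      scale(X)[1:21, perm], y[1:21],
                      scale(X)[22:30, perm], y[22:30])
  expect_equal(r1@accuracyPre, r2@accuracyPre)
  expect_equal(r1@aucMacro, r2@aucMacro, tolerance = 1e-10)
  expect_equal(r1@confusion, r2@confusion)
})

test_that("SVM grid search solves XOR and honors its contract", {
  set.seed(85)
  n <- 80
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  X <- scale(cbind(x1, x2))
  y <- factor(ifelse(x1 * x2 > 0, "p", "q"))
  fit <- svmTrain(X, y, CGrid = c(0.1, 1, 10), gGrid = c(0.1, 1, 10),
                  seed = 1)
  expect_true(attr(fit, "C") %in% c(0.1, 1, 10))
  expect_true(attr(fit, "g") %in% c(0.1, 1, 10))
  acc <- max(attr(fit, "gridAccuracy")$accuracy)
  expect_gt(acc, 0.9)

  # refitting on identical input is deterministic; duplicating the
  # training set (which rescales the effective penalty) leaves the
  # decision function essentially unchanged
  set.seed(86)
  Xnew <- scale(matrix(runif(40, -1, 1), 20, 2))
  refit <- svmTrain(X, y, CGrid = c(0.1, 1, 10), gGrid = c(0.1, 1, 10),
                    seed = 1)
  expect_equal(svmPredict(fit, Xnew)$labels, svmPredict(refit, Xnew)$labels)
  fit2 <- svmTrain(rbind(X, X), factor(c(as.character(y),
                                         as.character(y))), seed = 1)
  expect_gte(mean(svmPredict(fit, Xnew)$labels ==
                    svmPredict(fit2, Xnew)$labels), 0.9)

  expect_error(svmTrain(X, factor(rep("p", n)), seed = 1), "single-class")
})

test_that("cross-validation is stratified, leakage-free and chance-level on permuted labels", {
  set.seed(87)
  d <- twoClusters(n = 30, sep = 5)
  cv <- crossValidate(list(type = "plsda", nLatent = 1), d$X, d$y,
                      times = 2, folds = 5, seed = 1)
  expect_equal(cv$mean, 1)
  expect_equal(cv$nFolds, 10L)

  # fold sizes differ by <= 1 per class
  foldId <- hsifuse:::.stratifiedFolds(d$y, 5L, 3L)
  tab <- table(foldId, d$y)
  expect_lte(max(apply(tab, 2, function(x) diff(range(x)))), 1)

  # label permutation: accuracy near chance (1/2 here), across seeds
  set.seed(88)
  accs <- vapply(1:10, function(s) {
    yPerm <- sample(d$y)
    crossValidate(list(type = "plsda", nLatent = 2), d$X, yPerm,
                  times = 2, folds = 5, seed = s)$mean
  }, numeric(1L))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("per-fold selector refits inside the training fold only", {
  set.seed(89)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- factor(rep(c("a", "b"), each = 15))
  X[, 4] <- ifelse(y == "a", 2, -2) + rnorm(30, 0, 0.1)
  seen <- new.env(); seen$n <- 0L
  selector <- function(Xtr, ytr) {
    seen$n <- seen$n + 1L
    expect_lt(nrow(Xtr), 30L)
    which(abs(cor(Xtr, as.integer(ytr))) > 0.8)
  }
  cv <- crossValidate(list(type = "plsda", nLatent = 1), X, y,
                      times = 1, folds = 5, seed = 1, selector = selector)
  expect_equal(seen$n, 5L)
  expect_gt(cv$mean, 0.9)
})

test_that("trapezoidal AUC matches rank statistics and pROC", {
  expect_equal(hsifuse:::.binaryAuc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # positives {0.9, 0.3} vs negatives {0.8, 0.4}: 2 of 4 pairs concordant
  expect_equal(hsifuse:::.binaryAuc(c(0.9, 0.3, 0.8, 0.4),
                                    c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # monotone transform invariance
  set.seed(90)
  s <- rnorm(40); pos <- runif(40) < 0.4
  pos[1:2] <- c(TRUE, FALSE)
  expect_equal(hsifuse:::.binaryAuc(s, pos),
               hsifuse:::.binaryAuc(exp(2 * s), pos))
  # ties handled as half-concordant, as in pROC
  skip_if_not_installed("pROC")
  for (rep in 1:5) {
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    p <- runif(30) < 0.4
    p[1:2] <- c(TRUE, FALSE)
    want <- as.numeric(pROC::auc(pROC::roc(response = p, predictor = s,
                                           quiet = TRUE,
                                           direction = "<")))
    expect_equal(hsifuse:::.binaryAuc(s, p), want, tolerance = 1e-12)
  }
})

test_that("multiclass macro AUC averages one-vs-rest AUCs", {
  set.seed(91)
  y <- factor(rep(c("a", "b", "c"), each = 10))
  scores <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, levels(y)))
  scores[cbind(1:30, as.integer(y))] <- scores[cbind(1:30, as.integer(y))] + 3
  auc <- rocAuc(scores, y)
  expect_length(auc$perClass, 3L)
  expect_equal(auc$macro, mean(auc$perClass))
  expect_true(all(auc$perClass > 0.9))
  crv <- rocCurve(scores[, 1], y == "a")
  expect_equal(crv$fpr[1], 0); expect_equal(crv$tpr[nrow(crv)], 1)
})

test_that("latent-count selection prefers parsimonious separating models", {
  d <- twoClusters(n = 24, sep = 6, seed = 92, p = 4)
  sel <- plsdaSelectLatent(d$X, d$y, candidates = 1:4, times = 2,
                           folds = 4, seed = 1)
  expect_equal(sel$nLatent, 1L)
  expect_equal(unname(sel$cvAccuracy["1"]), 1)
})
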