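## squared Euclidean distance matrices
sqDistMatrix <- function(X) {
  s <- rowSums(X^2)
  D <- outer(s, s, `+`) - 2 * tcrossprod(X)
  pmax(D, 0)
}

sqDistCross <- function(X, Z) {
  D <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * tcrossprod(X, Z)
  pmax(D, 0)
}

#' Train a Gaussian-kernel soft-margin SVM
#'
#' C-SVC with RBF kernel `k(x, z) = exp(-gamma ||x - z||^2)`. The dual
#' quadratic program (box constraints `0 <= alpha_i <= C`, equality
#' `sum alpha_i y_i = 0`) is solved with `quadprog::solve.QP`; a tiny ridge
#' is added to the kernel matrix for numerical positive-definiteness.
#'
#' @param X numeric matrix, subjects x features.
#' @param y class labels in {0, 1}; 1 is the positive (death-like) class.
#' @param C soft-margin cost.
#' @param gamma RBF kernel width parameter.
#' @param D optional precomputed squared-distance matrix of `X`.
#' @return A list of class `"svmModel"` with the support-vector expansion
#'   (`alpha`, `sv`, `svY`, `b`, `gamma`).
#' @export
svmFitRBF <- function(X, y, C, gamma, D = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(D)) D <- sqDistMatrix(X)
  fit <- svmDualQP(exp(-gamma * D), y, C)
  svIdx <- which(fit$alpha > fit$tol)
  structure(
    list(alpha = fit$alpha[svIdx], sv = X[svIdx, , drop = FALSE],
         svY = fit$ys[svIdx], b = fit$b, gamma = gamma, C = C),
    class = "svmModel"
  )
}

## dual QP on a precomputed kernel matrix; returns the full alpha vector
svmDualQP <- function(K, y, C) {
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  ys <- ifelse(y == 1L, 1, -1)
  n <- length(y)
  Dmat <- (ys %o% ys) * K
  diag(Dmat) <- diag(Dmat) + 1e-8
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  tol <- 1e-6 * C
  free <- which(alpha > tol & alpha < C - tol)
  f0 <- as.vector(K %*% (alpha * ys))
  b <- if (length(free)) {
    mean(ys[free] - f0[free])
  } else {
    # no free vectors: midpoint of the feasible bias interval
    up <- ys == 1 & alpha < C - tol | ys == -1 & alpha > tol
    lo <- ys == -1 & alpha < C - tol | ys == 1 & alpha > tol
    hi <- if (any(up)) min(ys[up] - f0[up]) else 0
    lw <- if (any(lo)) max(ys[lo] - f0[lo]) else 0
    (hi + lw) / 2
  }
  list(alpha = alpha, ys = ys, b = b, tol = tol)
}

#' Decision values of a fitted SVM
#'
#' @param model an `"svmModel"` from [svmFitRBF()].
#' @param X new data, subjects x features.
#' @return Numeric decision values; positive predicts class 1.
#' @export
svmDecision <- function(model, X) {
  X <- as.matrix(X)
  K <- exp(-model$gamma * sqDistCross(X, model$sv))
  as.vector(K %*% (model$alpha * model$svY)) + model$b
}

## deterministic stratified fold assignment from a seed; depends on labels
## only, so identical seeds give identical partitions across feature sets
stratifiedFolds <- function(y, nFolds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

## coarse-to-fine grid search over log2(C), log2(gamma) in [-5, 15]:
## stage 1 step 4, then step 2 and 1 centred on the best point. Selection
## by stratified inner-CV accuracy; ties resolved to the first (smallest)
## grid point for determinism.
gridSearchRBF <- function(X, y, nFolds = 3, seed = 1, stages = 3,
                          expRange = c(-5, 15)) {
  fold <- stratifiedFolds(y, nFolds, seed)
  # scaled data and distance matrices are grid-independent: compute once
  folds <- lapply(seq_len(nFolds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) return(NULL)
    sc <- scaleTrainTest(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    list(ytr = y[tr], yte = y[!tr],
         Dtr = sqDistMatrix(sc$train),
         Dcr = sqDistCross(sc$test, sc$train))
  })
  evalPoint <- function(lc, lg) {
    g <- 2^lg
    acc <- 0
    for (fd in folds) {
      if (is.null(fd)) next
      m <- svmDualQP(exp(-g * fd$Dtr), fd$ytr, 2^lc)
      dv <- as.vector(exp(-g * fd$Dcr) %*% (m$alpha * m$ys)) + m$b
      acc <- acc + sum((dv > 0) == (fd$yte == 1L))
    }
    acc
  }
  step <- 4
  grid <- expand.grid(lc = seq(expRange[1], expRange[2], by = step),
                      lg = seq(expRange[1], expRange[2], by = step))
  best <- NULL
  tried <- new.env(parent = emptyenv())
  for (stage in seq_len(stages)) {
    for (i in seq_len(nrow(grid))) {
      key <- paste(grid$lc[i], grid$lg[i])
      if (!is.null(tried[[key]])) next
      a <- evalPoint(grid$lc[i], grid$lg[i])
      tried[[key]] <- a
      if (is.null(best) || a > best$acc) {
        best <- list(lc = grid$lc[i], lg = grid$lg[i], acc = a)
      }
    }
    step <- step / 2
    if (stage < stages) {
      lcs <- seq(max(expRange[1], best$lc - 2 * step),
                 min(expRange[2], best$lc + 2 * step), by = step)
      lgs <- seq(max(expRange[1], best$lg - 2 * step),
                 min(expRange[2], best$lg + 2 * step), by = step)
      grid <- expand.grid(lc = lcs, lg = lgs)
    }
  }
  list(C = 2^best$lc, gamma = 2^best$lg, innerAccuracy = best$acc)
}

scaleTrainTest <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  sdv[sdv < .Machine$double.eps * 100] <- 1
  list(
    train = sweep(sweep(train, 2L, mu), 2L, sdv, `/`),
    test = sweep(sweep(test, 2L, mu), 2L, sdv, `/`)
  )
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP / (TP + FN)` (true-positive rate for the death-like
#' class), specificity `TN / (FP + TN)` and accuracy
#' `(TP + TN) / (TP + FN + FP + TN)`.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return A list with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' confusionMetrics(tp = 15, fn = 1, tn = 11, fp = 2)
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (fp + tn),
    accuracy = (tp + tn) / (tp + fn + fp + tn)
  )
}

#' ROC curve and AUC by the rank (Mann-Whitney) statistic
#'
#' The AUC equals the Mann-Whitney U statistic normalised by `n1 * n0`
#' (probability that a random positive outranks a random negative); tied
#' scores contribute 1/2.
#'
#' @param scores real-valued decision scores (larger = more positive).
#' @param labels class labels in {0, 1}; both classes must be present.
#' @return A list with `auc` and `curve`, a data.frame of
#'   (`fpr`, `tpr`) points swept over all score thresholds.
#' @examples
#' rocAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(labels[ord] == 1L) / n1)
  fpr <- c(0, cumsum(labels[ord] == 0L) / n0)
  keep <- !duplicated(c(-Inf, scores[ord]), fromLast = TRUE)
  list(auc = auc, curve = data.frame(fpr = fpr[keep], tpr = tpr[keep]))
}

#' Leave-one-out SVM evaluation with nested grid search
#'
#' For each left-out subject, hyperparameters (C, gamma) are chosen by a
#' stratified inner cross-validation and coarse-to-fine grid search on the
#' remaining subjects only (no leakage), features are z-scored with
#' training-fold statistics, and the subject's decision score is recorded.
#' Scores pooled across folds form the ROC; the confusion matrix is taken
#' at decision threshold 0.
#'
#' @param X numeric matrix, subjects x features.
#' @param y class labels in {0, 1}; 1 is the positive (death-like) class.
#' @param innerFolds inner CV fold count (default 3).
#' @param seed RNG seed for the inner fold assignment (LOO itself is
#'   deterministic).
#' @param stages grid-search refinement stages (default 3).
#' @return A [ClassifierReport-class].
#' @export
evaluateLOOCV <- function(X, y, innerFolds = 3, seed = 1, stages = 3) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("need both classes")
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class")
  n <- nrow(X)
  scores <- numeric(n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    gs <- gridSearchRBF(X[tr, , drop = FALSE], y[tr], nFolds = innerFolds,
                        seed = seed + i, stages = stages)
    sc <- scaleTrainTest(X[tr, , drop = FALSE], X[i, , drop = FALSE])
    m <- svmFitRBF(sc$train, y[tr], C = gs$C, gamma = gs$gamma)
    scores[i] <- svmDecision(m, sc$test)
    params[[i]] <- data.frame(fold = i, C = gs$C, gamma = gs$gamma)
  }
  pred <- as.integer(scores > 0)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  met <- confusionMetrics(tp, fn, tn, fp)
  new("ClassifierReport",
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = met$sensitivity, specificity = met$specificity,
    accuracy = met$accuracy, auc = rocAUC(scores, y)$auc,
    scores = scores, labels = y,
    foldParams = do.call(rbind, params)
  )
}

#' Evaluate several feature sets under identical cross-validation
#'
#' Runs [evaluateLOOCV()] on each feature set with the same labels, the
#' same (deterministic) leave-one-out partition and the same seed for the
#' inner folds, so set comparisons are fair.
#'
#' @param sets named list of subjects x features matrices (e.g. the
#'   `set1`..`set4` element of [assembleFeatureSets()]).
#' @param y class labels in {0, 1}.
#' @param innerFolds inner CV fold count.
#' @param seed RNG seed shared across sets.
#' @param stages grid-search stages.
#' @return A list with `reports` (one [ClassifierReport-class] per set) and
#'   `summary`, a data.frame of accuracy/sensitivity/specificity/AUC per
#'   set.
#' @export
compareFeatureSets <- function(sets, y, innerFolds = 3, seed = 1,
                               stages = 3) {
  sets <- sets[vapply(sets, is.matrix, logical(1))]
  reports <- lapply(sets, evaluateLOOCV, y = y, innerFolds = innerFolds,
                    seed = seed, stages = stages)
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(
      set = nm, accuracy = r@accuracy, sensitivity = r@sensitivity,
      specificity = r@specificity, auc = r@auc, stringsAsFactors = FALSE
    )
  }))
  list(reports = reports, summary = summary)
}
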