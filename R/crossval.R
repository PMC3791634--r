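## Stratified k-fold splitting, the cross-validation accuracy that serves
## as the swarm's fitness, and the confusion-matrix metrics. Positive class
## is abnormal (+1), negative is normal (-1).

#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals its members round-robin across
#' folds, rotating the starting fold between classes so overall fold sizes
#' stay within one of each other. With 90 samples (5 normal, 85 abnormal)
#' and k = 5 every fold holds 18 samples including exactly one normal, so
#' across the 5 fold rotations 360 assignments are training and 90
#' validation. Classes with fewer than k members simply appear in only some
#' folds.
#'
#' @param labels vector of class labels (any type).
#' @param k number of folds; default 5.
#' @param seed optional integer seed.
#' @return a [FoldPlan-class].
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = NULL) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  assignments <- integer(n)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    assignments[idx] <- folds
    offset <- (offset + length(idx)) %% k
  }
  new("FoldPlan", k = k, assignments = assignments,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Per-fold standardize/reduce cache
#'
#' Precomputes, for every fold of a plan, the standardized and
#' PCA-projected training and validation feature blocks. Hyperparameter
#' search evaluates many (C, sigma) pairs against the same folds, so this
#' preparation is done once and shared. With \code{pcaScope = "per_fold"}
#' (default) standardization and PCA are fitted on each fold's training
#' portion only, avoiding information leakage from the held-out part;
#' \code{"global"} fits them once on all samples first.
#'
#' @param X n x p raw feature matrix.
#' @param y labels in \{-1, +1\}.
#' @param plan a [FoldPlan-class] matching \code{nrow(X)}.
#' @param varianceTarget cumulative explained-variance fraction for
#'   [selectComponents()].
#' @param pcaScope \code{"per_fold"} or \code{"global"}.
#' @return list of k fold entries, each with \code{trainX}, \code{trainY},
#'   \code{testX}, \code{testY}, \code{k} (components used).
#' @export
prepareFolds <- function(X, y, plan, varianceTarget = 0.95,
                         pcaScope = c("per_fold", "global")) {
  pcaScope <- match.arg(pcaScope)
  X <- as.matrix(X)
  if (nrow(X) != length(plan@assignments))
    stop("fold plan does not match the data size", call. = FALSE)
  if (pcaScope == "global") {
    reducer <- fitReducer(X)
    kg <- selectComponents(reducer, varianceTarget)
    S <- projectPCA(X, reducer, kg)
  }
  lapply(seq_len(plan@k), function(f) {
    te <- plan@assignments == f
    tr <- !te
    if (length(unique(y[tr])) < 2L)
      stop(sprintf("fold %d training portion holds a single class", f),
           call. = FALSE)
    if (pcaScope == "per_fold") {
      reducer <- fitReducer(X[tr, , drop = FALSE])
      kf <- selectComponents(reducer, varianceTarget)
      list(trainX = projectPCA(X[tr, , drop = FALSE], reducer, kf),
           trainY = y[tr],
           testX = projectPCA(X[te, , drop = FALSE], reducer, kf),
           testY = y[te], k = kf)
    } else {
      list(trainX = S[tr, , drop = FALSE], trainY = y[tr],
           testX = S[te, , drop = FALSE], testY = y[te], k = kg)
    }
  })
}

#' Cross-validation accuracy fitness
#'
#' The objective the hyperparameter search maximizes: for every fold, fit
#' the feature reducer and an RBF-kernel SVM at (C, sigma) on the training
#' portion, predict the held-out portion, and average the k fold
#' accuracies, i.e. \eqn{\frac1k \sum_i y_s^{(i)} / (y_s^{(i)} +
#' y_m^{(i)})} with \eqn{y_s, y_m} the per-fold success and
#' misclassification counts. With equal fold sizes this mean equals the
#' pooled accuracy.
#'
#' @inheritParams prepareFolds
#' @param C,sigma SVM penalty and RBF width.
#' @param folds optional precomputed [prepareFolds()] output; when given,
#'   \code{X}, \code{y} and \code{plan} are ignored.
#' @param trainFun classifier constructor used per fold, by default the
#'   RBF-kernel SVM: \code{function(trainX, trainY)} returning an object
#'   whose \code{predict(object, testX)} yields labels. Injectable for
#'   testing.
#' @param tol SMO KKT tolerance passed to [trainKSVM()].
#' @return mean held-out accuracy in [0, 1].
#' @export
cvFitness <- function(X, y, C, sigma, plan, varianceTarget = 0.95,
                      pcaScope = c("per_fold", "global"), folds = NULL,
                      trainFun = NULL, tol = 1e-3) {
  if (is.null(folds))
    folds <- prepareFolds(X, y, plan, varianceTarget, match.arg(pcaScope))
  if (is.null(trainFun))
    trainFun <- function(trainX, trainY)
      trainKSVM(trainX, trainY, C = C, kernel = rbfKernel(sigma),
                tol = tol)
  acc <- vapply(folds, function(f) {
    model <- trainFun(f$trainX, f$trainY)
    mean(predict(model, f$testX) == f$testY)
  }, numeric(1))
  mean(acc)
}

#' Confusion matrix and derived rates
#'
#' Counts with abnormal (+1) as the positive class:
#' sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
#' accuracy = (tp + tn) / n. A rate whose reference class is absent is
#' reported as \code{NA}, not 0.
#'
#' @param yTrue,yPred equal-length label vectors in \{-1, +1\}.
#' @return list with \code{confusion} (named counts tp, fn, fp, tn),
#'   \code{sensitivity}, \code{specificity}, \code{accuracy}.
#' @examples
#' # arithmetic of a printed confusion matrix: 417/8/2/23 of 450
#' p <- rep(c(1, -1, 1, -1), c(417, 8, 2, 23))
#' t <- rep(c(1, -1), c(425, 25))
#' confusionMetrics(t, p)$accuracy  # 0.9778
#' @export
confusionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) == 0L)
    stop("empty input", call. = FALSE)
  if (length(yTrue) != length(yPred))
    stop("label vectors must have equal length", call. = FALSE)
  if (!all(c(yTrue, yPred) %in% c(-1, 1)))
    stop("labels must be -1/+1", call. = FALSE)
  tp <- sum(yTrue == 1 & yPred == 1)
  fn <- sum(yTrue == 1 & yPred == -1)
  fp <- sum(yTrue == -1 & yPred == 1)
  tn <- sum(yTrue == -1 & yPred == -1)
  list(
    confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(yTrue)
  )
}

#' @rdname FoldPlan-class
#' @param object a \code{FoldPlan}.
#' @export
setMethod("show", "FoldPlan", function(object) {
  sz <- tabulate(object@assignments, object@k)
  cat(sprintf("FoldPlan: %d folds over %d samples (sizes %s)\n",
              object@k, length(object@assignments),
              paste(sz, collapse = ", ")))
})
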