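## Soft-margin kernel SVM trained in the dual by sequential minimal
## optimization (compiled, src/smo.cpp). The RBF kernel follows the
## sigma^2-denominator convention: k(x,z) = exp(-||x-z||^2 / sigma^2),
## i.e. gamma = 1/sigma^2 in libsvm terms.

#' Kernel constructors
#'
#' @param sigma positive RBF width (sigma^2 denominator convention).
#' @return a [KernelSpec-class].
#' @examples
#' kernelEval(1, 1 + 1, rbfKernel(1))  # exp(-1)
#' @export
rbfKernel <- function(sigma) new("KernelSpec", kind = "rbf",
                                 sigma = as.numeric(sigma))

#' @rdname rbfKernel
#' @export
linearKernel <- function() new("KernelSpec", kind = "linear",
                               sigma = NA_real_)

#' Evaluate a kernel on a pair of vectors
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param spec a [KernelSpec-class].
#' @return scalar kernel value; for rbf,
#'   \eqn{\exp(-\|x_1-x_2\|^2/\sigma^2)}, for linear the dot product.
#' @export
kernelEval <- function(x1, x2, spec) {
  if (length(x1) != length(x2))
    stop("kernel arguments must have equal dimension", call. = FALSE)
  switch(spec@kind,
    linear = sum(x1 * x2),
    rbf = exp(-sum((x1 - x2)^2) / spec@sigma^2))
}

#' Kernel Gram matrix
#'
#' @param X1 n1 x p matrix.
#' @param X2 n2 x p matrix; defaults to \code{X1}.
#' @param spec a [KernelSpec-class].
#' @return n1 x n2 matrix of pairwise kernel values.
#' @export
kernelMatrix <- function(X1, X2 = NULL, spec) {
  X1 <- as.matrix(X1)
  X2 <- if (is.null(X2)) X1 else as.matrix(X2)
  if (ncol(X1) != ncol(X2))
    stop("kernel arguments must have equal dimension", call. = FALSE)
  if (spec@kind == "linear") return(tcrossprod(X1, X2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0   # numerical floor
  exp(-d2 / spec@sigma^2)
}

#' Train a soft-margin kernel SVM
#'
#' Solves the dual quadratic program
#' \deqn{\max_\alpha \sum_n \alpha_n - \tfrac12 \sum_{m,n}
#'   \alpha_m\alpha_n y_m y_n k(x_m,x_n),\quad
#'   0\le\alpha_n\le C,\ \textstyle\sum_n \alpha_n y_n = 0}
#' with a deterministic SMO solver to KKT tolerance \code{tol}. The bias is
#' recovered by averaging \eqn{s(x_n) - y_n} over margin support vectors
#' (\eqn{0 < \alpha_n < C}); when every multiplier is at a bound, the
#' midpoint of the KKT-feasible bias interval is used. Points with
#' \eqn{\alpha_n > 10^{-8} C} are retained as support vectors.
#'
#' @param X n x p feature matrix.
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param C positive box-constraint penalty.
#' @param kernel a [KernelSpec-class]; default RBF with \code{sigma}.
#' @param sigma convenience RBF width used when \code{kernel} is missing.
#' @param tol KKT tolerance of the solver.
#' @return a [KSVMModel-class].
#' @examples
#' X <- matrix(c(-1, 1), 2, 1)
#' m <- trainKSVM(X, c(-1, 1), C = 100, kernel = linearKernel())
#' decisionFunction(m, matrix(0))  # 0: midpoint of the margin
#' @export
trainKSVM <- function(X, y, C, kernel = rbfKernel(sigma), sigma = 1,
                      tol = 1e-3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  if (nrow(X) != length(y))
    stop("X rows must match label length", call. = FALSE)
  if (!is.finite(C) || C <= 0)
    stop("C must be positive", call. = FALSE)
  K <- kernelMatrix(X, spec = kernel)
  sol <- .smoSolve(K, y, C, tol)
  if (!sol$converged)
    warning("SMO step budget exhausted before full KKT convergence")
  alpha <- sol$alpha
  av <- alpha * y
  s <- as.vector(K %*% av)           # f(x_n) = s_n - b
  free <- alpha > 1e-8 * C & alpha < C * (1 - 1e-8)
  if (any(free)) {
    b <- mean(s[free] - y[free])
  } else {
    # all multipliers at bounds: any b in [lo, hi] satisfies the KKT system
    lo <- suppressWarnings(max(c(s - 1)[y > 0 & alpha > C / 2],
                               (s + 1)[y < 0 & alpha < C / 2]))
    hi <- suppressWarnings(min(c(s - 1)[y > 0 & alpha < C / 2],
                               (s + 1)[y < 0 & alpha > C / 2]))
    b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else sol$b
  }
  obj <- sum(alpha) - 0.5 * sum(av * (K %*% av))
  keep <- alpha > 1e-8 * C
  new("KSVMModel",
      supportVectors = X[keep, , drop = FALSE],
      dualCoef = av[keep], alphas = alpha[keep], bias = b,
      kernel = kernel, cost = C, objective = obj)
}

#' SVM decision values
#'
#' \eqn{f(x) = \sum_n \alpha_n y_n k(x_n, x) - b}; the sign is the
#' predicted class.
#'
#' @param model a [KSVMModel-class].
#' @param X matrix of points to evaluate (rows), or a single vector.
#' @return numeric vector of decision values.
#' @export
decisionFunction <- function(model, X) {
  stopifnot(is(model, "KSVMModel"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@supportVectors))
    stop("feature dimension does not match the model", call. = FALSE)
  as.vector(kernelMatrix(X, model@supportVectors, model@kernel) %*%
              model@dualCoef) - model@bias
}

#' Predict class labels
#'
#' @param object a [KSVMModel-class].
#' @param newdata matrix of points (rows) or a single vector.
#' @param ... unused.
#' @return labels in \{-1, +1\}; a decision value of exactly zero maps
#'   to +1.
#' @export
setMethod("predict", "KSVMModel", function(object, newdata, ...) {
  f <- decisionFunction(object, newdata)
  ifelse(f >= 0, 1, -1)
})

#' @describeIn KSVMModel-class retained training points.
#' @param object a \code{KSVMModel}.
#' @export
setGeneric("supportVectors", function(object)
  standardGeneric("supportVectors"))

#' @rdname KSVMModel-class
#' @export
setMethod("supportVectors", "KSVMModel", function(object)
  object@supportVectors)

#' @rdname KSVMModel-class
#' @export
setMethod("show", "KSVMModel", function(object) {
  kd <- if (object@kernel@kind == "rbf")
    sprintf("rbf (sigma = %.4g)", object@kernel@sigma) else "linear"
  cat(sprintf(
    "KSVMModel: %s kernel, C = %.4g\n  %d support vectors, bias %.4g, dual objective %.6g\n",
    kd, object@cost, nrow(object@supportVectors), object@bias,
    object@objective))
})
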