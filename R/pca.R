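## Feature standardization and principal-component reduction.
## Conventions fixed here and relied on by the rest of the package:
## sample (n-1) denominators throughout; zero-variance features are centered
## but not scaled; component signs are fixed by making the largest-magnitude
## loading of each column positive.

#' Standardize a feature matrix
#'
#' Centers each feature to mean zero and scales to unit sample variance
#' (denominator n-1). Features with zero variance are centered only. When
#' \code{center}/\code{scale} are supplied (training statistics), they are
#' applied instead of being estimated, as required when transforming
#' held-out data.
#'
#' @param X sample-by-feature numeric matrix.
#' @param center,scale optional per-feature statistics from a previous fit;
#'   both or neither must be given.
#' @return standardized matrix with attributes \code{"center"} and
#'   \code{"scale"} holding the statistics used.
#' @examples
#' standardizeFeatures(matrix(c(0, 2), 2, 1))  # -1, 1
#' @export
standardizeFeatures <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center) != is.null(scale))
    stop("supply both center and scale, or neither", call. = FALSE)
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1   # zero-variance guard
  } else {
    if (length(center) != ncol(X) || length(scale) != ncol(X))
      stop("feature count does not match standardization statistics",
           call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  Z
}

#' Fit a principal component model
#'
#' Computes the orthonormal components of the sample covariance of \code{X}
#' via singular value decomposition (numerically preferable to an explicit
#' eigendecomposition when features far outnumber samples), ordered by
#' decreasing variance. \code{X} is centered internally; it is normally
#' already standardized via [standardizeFeatures()].
#'
#' @param X sample-by-feature matrix with at least two rows.
#' @return a [PCAModel-class] with \code{min(n-1, p)} components.
#' @examples
#' m <- fitPCA(matrix(rnorm(50), 10, 5))
#' sum(explainedVariance(m))  # 1
#' @export
fitPCA <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L)
    stop("PCA needs at least two samples", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  r <- min(n - 1L, ncol(X))
  sv <- svd(Xc, nu = 0, nv = r)
  sdev <- sv$d[seq_len(r)] / sqrt(n - 1)
  rotation <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) rotation[, j] <- -rotation[, j]
  }
  tot <- sum(sdev^2)
  ratio <- if (tot > 0) sdev^2 / tot else rep(0, r)
  new("PCAModel", center = center, scale = rep(1, ncol(X)),
      rotation = rotation, sdev = sdev, varianceRatio = ratio,
      nSamples = as.integer(n))
}

#' Fit standardization and PCA in one step
#'
#' Convenience used by the pipeline: standardizes \code{X}, fits the PCA on
#' the standardized data, and folds the standardization statistics into the
#' returned model so [projectPCA()] can be applied directly to raw feature
#' matrices.
#'
#' @inheritParams fitPCA
#' @return a [PCAModel-class] whose \code{center}/\code{scale} are the
#'   standardization statistics.
#' @export
fitReducer <- function(X) {
  Z <- standardizeFeatures(X)
  m <- fitPCA(Z)
  m@center <- attr(Z, "center")
  m@scale <- attr(Z, "scale")
  m
}

#' Number of components for a variance target
#'
#' @param model a [PCAModel-class].
#' @param varianceTarget fraction in (0, 1]; default 0.95.
#' @return the smallest k whose cumulative explained-variance ratio reaches
#'   the target (at least 1).
#' @examples
#' # ratios 0.6, 0.3, 0.1 -> 2 components reach 90%
#' @export
selectComponents <- function(model, varianceTarget = 0.95) {
  stopifnot(is(model, "PCAModel"))
  if (varianceTarget <= 0 || varianceTarget > 1)
    stop("varianceTarget must be in (0, 1]", call. = FALSE)
  cum <- cumsum(model@varianceRatio)
  k <- which(cum >= varianceTarget - 1e-12)[1]
  if (is.na(k)) k <- length(cum)   # rank-deficient: take everything
  max(1L, as.integer(k))
}

#' Project onto the leading principal components
#'
#' @param X raw sample-by-feature matrix (same features the model was
#'   fitted on).
#' @param model a [PCAModel-class].
#' @param k number of components to keep; defaults to all.
#' @return n x k score matrix.
#' @export
projectPCA <- function(X, model, k = ncol(model@rotation)) {
  stopifnot(is(model, "PCAModel"))
  X <- as.matrix(X)
  if (ncol(X) != nrow(model@rotation))
    stop("feature count does not match the PCA model", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > ncol(model@rotation))
    stop("k out of range", call. = FALSE)
  Z <- sweep(sweep(X, 2L, model@center, "-"), 2L, model@scale, "/")
  Z %*% model@rotation[, seq_len(k), drop = FALSE]
}

#' @describeIn PCAModel-class explained-variance fractions, one per
#'   component, non-increasing.
#' @param object a \code{PCAModel}.
#' @export
setGeneric("explainedVariance", function(object)
  standardGeneric("explainedVariance"))

#' @rdname PCAModel-class
#' @export
setMethod("explainedVariance", "PCAModel", function(object)
  object@varianceRatio)

#' @rdname PCAModel-class
#' @export
setMethod("show", "PCAModel", function(object) {
  k95 <- selectComponents(object, 0.95)
  cat(sprintf(
    "PCAModel: %d features, %d components (fit on %d samples)\n  95%% variance at %d components\n",
    nrow(object@rotation), ncol(object@rotation), object@nSamples, k95))
})
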