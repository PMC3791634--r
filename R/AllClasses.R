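#' @import methods
#' @importFrom stats runif rnorm sd predict
#' @importFrom Rcpp sourceCpp
#' @useDynLib brainKSVM, .registration = TRUE
NULL

#' Multilevel 2D wavelet decomposition
#'
#' Holds the output of a decimated multilevel 2D discrete wavelet transform:
#' the final approximation (LL) block and, for every level, the three detail
#' blocks. Level 1 is the finest scale. Subband dimensions halve (with
#' ceiling) from one level to the next.
#'
#' @slot levels number of decomposition levels J.
#' @slot approximation the level-J LL coefficient matrix.
#' @slot details list of length J; element j is a list with matrices
#'   \code{LH} (low-pass rows, high-pass columns), \code{HL} and \code{HH}.
#' @slot boundaryMode boundary extension used for odd-sized inputs:
#'   \code{"symmetric"}, \code{"periodic"} or \code{"zero"}.
#' @slot inputDim original image dimensions (rows, cols), needed for exact
#'   inverse reconstruction.
#'
#' @seealso [waveletDecompose()], [waveletReconstruct()]
#' @export
setClass("WaveletPyramid",
  representation(
    levels = "integer",
    approximation = "matrix",
    details = "list",
    boundaryMode = "character",
    inputDim = "integer"
  )
)

setValidity("WaveletPyramid", function(object) {
  msg <- character()
  if (length(object@details) != object@levels)
    msg <- c(msg, "details must hold one entry per level")
  if (!object@boundaryMode %in% c("symmetric", "periodic", "zero"))
    msg <- c(msg, "unknown boundaryMode")
  for (j in seq_along(object@details)) {
    d <- object@details[[j]]
    if (!all(c("LH", "HL", "HH") %in% names(d)))
      msg <- c(msg, sprintf("level %d detail blocks incomplete", j))
  }
  if (length(msg)) msg else TRUE
})

#' Standardization + principal component model
#'
#' Per-feature centering/scaling statistics together with an orthonormal
#' rotation ordered by decreasing explained variance. Fitted by [fitPCA()];
#' by convention the rotation is fitted on standardized data, so
#' \code{center} is essentially zero and \code{scale} is all ones unless the
#' model was built through [fitReducer()], which folds the standardization in.
#'
#' @slot center per-feature mean subtracted before rotation.
#' @slot scale per-feature divisor applied before rotation (1 for
#'   zero-variance features).
#' @slot rotation d_in x r orthonormal matrix of component loadings, columns
#'   ordered by decreasing variance; sign fixed so each column's
#'   largest-magnitude loading is positive.
#' @slot sdev standard deviation of the data along each component.
#' @slot varianceRatio fraction of total variance per component (sums to 1
#'   over all components with nonzero variance).
#' @slot nSamples number of samples the model was fitted on.
#'
#' @seealso [fitPCA()], [selectComponents()], [projectPCA()]
#' @export
setClass("PCAModel",
  representation(
    center = "numeric",
    scale = "numeric",
    rotation = "matrix",
    sdev = "numeric",
    varianceRatio = "numeric",
    nSamples = "integer"
  )
)

setValidity("PCAModel", function(object) {
  msg <- character()
  r <- ncol(object@rotation)
  if (length(object@sdev) != r || length(object@varianceRatio) != r)
    msg <- c(msg, "sdev/varianceRatio length must match rotation columns")
  if (length(object@center) != nrow(object@rotation))
    msg <- c(msg, "center length must match rotation rows")
  if (r > 1 && any(diff(object@varianceRatio) > 1e-8))
    msg <- c(msg, "varianceRatio must be non-increasing")
  G <- crossprod(object@rotation)
  if (max(abs(G - diag(r))) > 1e-6)
    msg <- c(msg, "rotation columns must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Kernel specification
#'
#' @slot kind \code{"linear"} or \code{"rbf"}.
#' @slot sigma RBF width; the kernel is \eqn{k(x,z) = \exp(-\|x-z\|^2 /
#'   \sigma^2)} — note the \eqn{\sigma^2} denominator with no factor of 2,
#'   so for libsvm-style parameterizations \eqn{\gamma = 1/\sigma^2}.
#'
#' @seealso [rbfKernel()], [linearKernel()], [kernelEval()]
#' @export
setClass("KernelSpec",
  representation(kind = "character", sigma = "numeric")
)

setValidity("KernelSpec", function(object) {
  if (!object@kind %in% c("linear", "rbf"))
    return("kind must be 'linear' or 'rbf'")
  if (object@kind == "rbf" &&
      (length(object@sigma) != 1 || !is.finite(object@sigma) ||
       object@sigma <= 0))
    return("sigma must be a single positive number")
  TRUE
})

#' Trained soft-margin kernel SVM
#'
#' Solution of the dual problem
#' \deqn{\max_\alpha \sum_n \alpha_n - \tfrac12 \sum_{m,n} \alpha_m \alpha_n
#'   y_m y_n k(x_m, x_n), \quad 0 \le \alpha_n \le C,\ \sum_n \alpha_n y_n = 0}
#' compacted to its support vectors. The decision function is
#' \eqn{f(x) = \sum_n \alpha_n y_n k(x_n, x) - b}.
#'
#' @slot supportVectors m x p matrix of retained training points.
#' @slot dualCoef \eqn{\alpha_n y_n} for each support vector.
#' @slot alphas the \eqn{\alpha_n} themselves.
#' @slot bias the offset b.
#' @slot kernel a [KernelSpec-class].
#' @slot cost box-constraint penalty C.
#' @slot objective dual objective value at the solution.
#'
#' @seealso [trainKSVM()], [decisionFunction()]
#' @export
setClass("KSVMModel",
  representation(
    supportVectors = "matrix",
    dualCoef = "numeric",
    alphas = "numeric",
    bias = "numeric",
    kernel = "KernelSpec",
    cost = "numeric",
    objective = "numeric"
  )
)

setValidity("KSVMModel", function(object) {
  msg <- character()
  m <- nrow(object@supportVectors)
  if (length(object@dualCoef) != m || length(object@alphas) != m)
    msg <- c(msg, "dualCoef/alphas length must match supportVectors rows")
  if (any(object@alphas < -1e-8) ||
      any(object@alphas > object@cost * (1 + 1e-6) + 1e-8))
    msg <- c(msg, "alphas must lie in [0, C]")
  if (length(msg)) msg else TRUE
})

#' Stratified fold assignment
#'
#' A partition of sample indices into k mutually exclusive, exhaustive folds,
#' stratified per class: fold sizes differ by at most one overall and at most
#' one within each class.
#'
#' @slot k number of folds.
#' @slot assignments per-sample fold index in 1..k.
#' @slot seed RNG seed the plan was drawn with (NA if none).
#'
#' @seealso [stratifiedKFold()]
#' @export
setClass("FoldPlan",
  representation(k = "integer", assignments = "integer", seed = "integer")
)

setValidity("FoldPlan", function(object) {
  a <- object@assignments
  if (any(a < 1L | a > object@k))
    return("assignments out of 1..k")
  sz <- tabulate(a, nbins = object@k)
  if (max(sz) - min(sz) > 1L)
    return("fold sizes must differ by at most one")
  TRUE
})

#' Synthetic brain-phantom specification
#'
#' Parameters of the two-class phantom generator: smooth elliptical
#' "brain" images on a [0,1] intensity scale, where the abnormal class adds
#' hyperintense lesion disks inside the brain mask. Defaults mirror a
#' 90-slice study set with a 5 normal / 85 abnormal imbalance.
#'
#' @slot size image side length in pixels.
#' @slot nNormal,nAbnormal class counts for [generatePhantomDataset()].
#' @slot lesionCountRange integer range of lesions per abnormal image.
#' @slot lesionRadiusRange lesion radius range in pixels.
#' @slot lesionContrast additive lesion intensity on the [0,1] scale.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot seed RNG seed used by [generatePhantomDataset()].
#'
#' @seealso [phantomSpec()], [generatePhantom()], [generatePhantomDataset()]
#' @export
setClass("PhantomSpec",
  representation(
    size = "integer",
    nNormal = "integer",
    nAbnormal = "integer",
    lesionCountRange = "integer",
    lesionRadiusRange = "numeric",
    lesionContrast = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@size < 8L) msg <- c(msg, "size must be at least 8")
  if (object@lesionContrast < 0) msg <- c(msg, "lesionContrast must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@lesionCountRange) != 2L ||
      any(object@lesionCountRange < 0L))
    msg <- c(msg, "lesionCountRange must be two non-negative counts")
  if (length(object@lesionRadiusRange) != 2L ||
      any(object@lesionRadiusRange <= 0) ||
      object@lesionRadiusRange[2] > 0.35 * object@size)
    msg <- c(msg, "lesionRadiusRange must be positive and fit the image")
  if (length(msg)) msg else TRUE
})

#' Particle swarm state
#'
#' @slot positions n x d particle positions.
#' @slot velocities n x d particle velocities.
#' @slot pbestPositions per-particle best positions seen so far.
#' @slot pbestFitness fitness at the personal bests (-Inf before the first
#'   evaluation).
#' @slot gbestPosition best position seen by any particle.
#' @slot gbestFitness fitness at the global best.
#' @slot w,c1,c2 inertia weight and acceleration coefficients of the
#'   velocity update.
#' @slot bounds d x 2 matrix of per-dimension limits.
#' @slot iteration number of [psoStep()] calls applied.
#'
#' @seealso [initSwarm()], [psoStep()], [psoOptimize()]
#' @export
setClass("Swarm",
  representation(
    positions = "matrix",
    velocities = "matrix",
    pbestPositions = "matrix",
    pbestFitness = "numeric",
    gbestPosition = "numeric",
    gbestFitness = "numeric",
    w = "numeric",
    c1 = "numeric",
    c2 = "numeric",
    bounds = "matrix",
    iteration = "integer"
  )
)

setValidity("Swarm", function(object) {
  msg <- character()
  d <- ncol(object@positions)
  if (!all(dim(object@velocities) == dim(object@positions)))
    msg <- c(msg, "velocities must match positions in shape")
  if (nrow(object@bounds) != d || ncol(object@bounds) != 2)
    msg <- c(msg, "bounds must be d x 2")
  if (any(object@bounds[, 2] <= object@bounds[, 1]))
    msg <- c(msg, "upper bounds must exceed lower bounds")
  lo <- matrix(object@bounds[, 1], nrow(object@positions), d, byrow = TRUE)
  hi <- matrix(object@bounds[, 2], nrow(object@positions), d, byrow = TRUE)
  if (any(object@positions < lo - 1e-12) || any(object@positions > hi + 1e-12))
    msg <- c(msg, "positions must lie within bounds")
  if (length(object@pbestFitness) &&
      is.finite(object@gbestFitness) &&
      abs(object@gbestFitness - max(object@pbestFitness)) > 1e-12)
    msg <- c(msg, "gbestFitness must equal the best pbestFitness")
  if (length(msg)) msg else TRUE
})

#' Fully trained classification system
#'
#' Output of [trainPipeline()]: the global feature reducer, the final kernel
#' SVM retrained on all data at the tuned (C*, sigma*), plus the search
#' provenance (fold plan, per-iteration fitness history, seeds and config)
#' needed to reproduce the run.
#'
#' @slot reducer the [PCAModel-class] holding standardization + rotation
#'   fitted on all training features.
#' @slot nComponents number of principal components retained.
#' @slot svm the final [KSVMModel-class].
#' @slot cost,sigma tuned hyperparameters (C*, sigma*).
#' @slot cvFitness cross-validation accuracy at (C, sigma) under the stored
#'   fold plan.
#' @slot history per-iteration global-best fitness of the swarm search.
#' @slot foldPlan the [FoldPlan-class] the fitness used.
#' @slot config the full pipeline configuration list (seeds included).
#' @slot imageDim expected input image dimensions.
#' @slot featureLength wavelet feature vector length.
#'
#' @seealso [trainPipeline()], [predict,TrainedSystem-method]
#' @export
setClass("TrainedSystem",
  representation(
    reducer = "PCAModel",
    nComponents = "integer",
    svm = "KSVMModel",
    cost = "numeric",
    sigma = "numeric",
    cvFitness = "numeric",
    history = "numeric",
    foldPlan = "FoldPlan",
    config = "list",
    imageDim = "integer",
    featureLength = "integer"
  )
)
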