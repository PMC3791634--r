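## End-to-end orchestration: wavelet features -> PCA reduction ->
## swarm-tuned RBF kernel SVM -> final model retrained on all data.

#' Pipeline configuration
#'
#' @param levels wavelet decomposition depth; 3 turns a 256 x 256 image
#'   into 1024 approximation features.
#' @param boundaryMode wavelet boundary extension.
#' @param varianceTarget cumulative explained-variance fraction the PCA
#'   step must preserve.
#' @param k cross-validation folds.
#' @param nParticles,nIter swarm size and iteration budget.
#' @param w,c1,c2 swarm inertia and acceleration coefficients; \code{w}
#'   may be \code{(w_start, w_end)} for the classic linearly decaying
#'   inertia schedule (the default), see [psoOptimize()].
#' @param CBounds search interval for the SVM penalty C.
#' @param sigmaBounds search interval for the RBF width sigma, interpreted
#'   per \code{sigmaScale}.
#' @param sigmaScale \code{"median"} (default): \code{sigmaBounds} are
#'   multiples of the median pairwise Euclidean distance between the
#'   reduced training features, making the kernel width scale-free;
#'   \code{"absolute"}: \code{sigmaBounds} are used as given.
#' @param pcaScope \code{"per_fold"} (default, leak-free) or
#'   \code{"global"} standardization/PCA for the CV fitness.
#' @param searchScale \code{"log"} (default): the swarm and the random
#'   baseline move in (log C, log sigma), the customary scale for SVM
#'   hyperparameters; \code{"linear"} searches the raw intervals, matching
#'   a uniform random-selection protocol on the printed ranges.
#' @param tol SMO KKT tolerance.
#' @param seed master seed; the fold plan uses \code{seed} and the swarm
#'   \code{seed + 1}.
#' @return configuration list consumed by [trainPipeline()].
#' @export
pipelineConfig <- function(levels = 3L, boundaryMode = "symmetric",
                           varianceTarget = 0.95, k = 5L,
                           nParticles = 20L, nIter = 50L,
                           w = c(0.9, 0.4), c1 = 1.49445, c2 = 1.49445,
                           CBounds = c(50, 200), sigmaBounds = c(0.25, 2),
                           sigmaScale = c("median", "absolute"),
                           pcaScope = c("per_fold", "global"),
                           searchScale = c("log", "linear"),
                           tol = 1e-3, seed = 1L) {
  list(levels = as.integer(levels), boundaryMode = boundaryMode,
       varianceTarget = varianceTarget, k = as.integer(k),
       nParticles = as.integer(nParticles), nIter = as.integer(nIter),
       w = w, c1 = c1, c2 = c2,
       CBounds = as.numeric(CBounds), sigmaBounds = as.numeric(sigmaBounds),
       sigmaScale = match.arg(sigmaScale), pcaScope = match.arg(pcaScope),
       searchScale = match.arg(searchScale),
       tol = tol, seed = as.integer(seed))
}

## Map the (C, sigma) box and fitness onto the configured search scale.
.searchSpace <- function(bounds, fitness, scale) {
  if (identical(scale, "linear"))
    return(list(bounds = bounds, fitness = fitness, decode = identity))
  list(bounds = log(bounds),
       fitness = function(q) fitness(exp(q)),
       decode = exp)
}

## Accept a manifest path, a manifest data.frame, or an in-memory dataset
## (list with $images and $labels) and return images + labels.
.resolveData <- function(data) {
  if (is.character(data) && length(data) == 1L)
    data <- readManifest(data)
  if (is.data.frame(data)) {
    images <- lapply(data$path, loadImage)
    return(list(images = images, labels = as.numeric(data$label)))
  }
  if (is.list(data) && !is.null(data$images) && !is.null(data$labels))
    return(list(images = data$images, labels = as.numeric(data$labels)))
  stop("data must be a manifest path, manifest data.frame, or a list ",
       "with $images and $labels", call. = FALSE)
}

.featureMatrix <- function(images, config) {
  dims <- unique(t(vapply(images, dim, integer(2))))
  if (nrow(dims) != 1L)
    stop("feature extraction: images differ in size", call. = FALSE)
  X <- t(vapply(images,
                function(im) extractFeatures(im, config$levels,
                                             config$boundaryMode),
                numeric(prod(ceiling(dims[1, ] / 2^config$levels)))))
  list(X = X, imageDim = as.integer(dims[1, ]))
}

## The median heuristic: sigma search bounds as multiples of the median
## pairwise distance between reduced feature vectors.
.sigmaBounds <- function(config, S) {
  if (config$sigmaScale == "absolute") return(config$sigmaBounds)
  config$sigmaBounds * stats::median(stats::dist(S))
}

#' Train the full classification system
#'
#' Runs the complete procedure: extract level-\code{levels} wavelet
#' approximation features from every image, build a stratified k-fold
#' plan, let a particle swarm maximize the cross-validated accuracy of an
#' RBF kernel SVM over (C, sigma), then retrain the feature reducer and
#' the SVM on all data at the tuned (C*, sigma*). The run is a pure
#' function of the input data and the configuration (all seeds derive
#' from \code{config$seed}).
#'
#' @param data manifest CSV path, manifest data.frame
#'   (\code{path}, \code{label}), or list with \code{$images} (matrices)
#'   and \code{$labels} (-1/+1) as produced by [generatePhantomDataset()].
#' @param config a [pipelineConfig()] list.
#' @param verbose print per-stage progress?
#' @return a [TrainedSystem-class].
#' @export
trainPipeline <- function(data, config = pipelineConfig(),
                          verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  d <- .resolveData(data)
  if (length(unique(d$labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  say("features: extracting from %d images", length(d$images))
  fm <- .featureMatrix(d$images, config)
  X <- fm$X
  stopifnot(ncol(X) == prod(ceiling(fm$imageDim / 2^config$levels)))

  plan <- stratifiedKFold(d$labels, config$k, seed = config$seed)
  say("crossval: %d-fold stratified plan (seed %d)", config$k, config$seed)
  folds <- prepareFolds(X, d$labels, plan, config$varianceTarget,
                        config$pcaScope)

  reducer <- fitReducer(X)
  nComp <- selectComponents(reducer, config$varianceTarget)
  S <- projectPCA(X, reducer, nComp)
  bounds <- rbind(config$CBounds, .sigmaBounds(config, S))
  say("pso: bounds C [%.4g, %.4g], sigma [%.4g, %.4g]",
      bounds[1, 1], bounds[1, 2], bounds[2, 1], bounds[2, 2])

  fitness <- function(p)
    cvFitness(C = p[1], sigma = p[2], folds = folds, tol = config$tol)
  sp <- .searchSpace(bounds, fitness, config$searchScale)
  opt <- psoOptimize(sp$fitness, sp$bounds, config$nParticles,
                     config$nIter, config$w, config$c1, config$c2,
                     seed = config$seed + 1L)
  best <- sp$decode(opt$bestPosition)
  say("pso: best fitness %.4f at C = %.4g, sigma = %.4g",
      opt$bestFitness, best[1], best[2])

  svm <- trainKSVM(S, d$labels, C = best[1], kernel = rbfKernel(best[2]),
                   tol = config$tol)
  config$effectiveBounds <- list(C = bounds[1, ], sigma = bounds[2, ])
  new("TrainedSystem", reducer = reducer, nComponents = as.integer(nComp),
      svm = svm, cost = best[1], sigma = best[2],
      cvFitness = opt$bestFitness, history = opt$history, foldPlan = plan,
      config = config, imageDim = fm$imageDim,
      featureLength = as.integer(ncol(X)))
}

#' Classify new images
#'
#' Applies the stored wavelet feature extraction, standardization, PCA
#' projection and SVM to new images. Images must match the training
#' raster size; a mismatch is an error (no silent resizing).
#'
#' @param object a [TrainedSystem-class].
#' @param newdata a single image matrix or a list of image matrices.
#' @param ... unused.
#' @return data.frame with \code{label} (-1/+1) and \code{decision} (the
#'   SVM decision value).
#' @export
setMethod("predict", "TrainedSystem", function(object, newdata, ...) {
  images <- if (is.matrix(newdata)) list(newdata) else newdata
  for (im in images)
    if (!all(dim(im) == object@imageDim))
      stop(sprintf("image size %d x %d does not match training size %d x %d",
                   nrow(im), ncol(im), object@imageDim[1],
                   object@imageDim[2]), call. = FALSE)
  X <- t(vapply(images,
                function(im) extractFeatures(im, object@config$levels,
                                             object@config$boundaryMode),
                numeric(object@featureLength)))
  S <- projectPCA(X, object@reducer, object@nComponents)
  f <- decisionFunction(object@svm, S)
  data.frame(label = ifelse(f >= 0, 1, -1), decision = f)
})

#' Repeated cross-validation evaluation of a trained system
#'
#' Re-runs k-fold cross-validation at the system's tuned (C*, sigma*),
#' \code{repeats} times with fresh fold plans, pooling the held-out
#' predictions. With r repeats of a 90-image 5-fold run the pooled
#' confusion matrix counts 90 r evaluations.
#'
#' @param system a [TrainedSystem-class].
#' @param data same forms as in [trainPipeline()].
#' @param repeats number of repeated CV experiments.
#' @param seed base seed for the fold plans (plan i uses
#'   \code{seed + i - 1}).
#' @return list with pooled \code{confusion}, \code{sensitivity},
#'   \code{specificity}, \code{accuracy}, and per-repeat fold accuracies
#'   in \code{foldAccuracy}.
#' @export
evaluateSystem <- function(system, data, repeats = 1L,
                           seed = system@config$seed) {
  stopifnot(is(system, "TrainedSystem"))
  d <- .resolveData(data)
  fm <- .featureMatrix(d$images, system@config)
  yTrue <- numeric(0)
  yPred <- numeric(0)
  foldAcc <- matrix(NA_real_, repeats, system@config$k)
  for (r in seq_len(repeats)) {
    plan <- stratifiedKFold(d$labels, system@config$k,
                            seed = seed + r - 1L)
    folds <- prepareFolds(fm$X, d$labels, plan,
                          system@config$varianceTarget,
                          system@config$pcaScope)
    for (f in seq_along(folds)) {
      m <- trainKSVM(folds[[f]]$trainX, folds[[f]]$trainY, C = system@cost,
                     kernel = rbfKernel(system@sigma),
                     tol = system@config$tol)
      p <- predict(m, folds[[f]]$testX)
      yTrue <- c(yTrue, folds[[f]]$testY)
      yPred <- c(yPred, p)
      foldAcc[r, f] <- mean(p == folds[[f]]$testY)
    }
  }
  out <- confusionMetrics(yTrue, yPred)
  out$foldAccuracy <- foldAcc
  out
}

#' Swarm search versus random selection
#'
#' The baseline comparison: for each seed, tune (C, sigma) once with the
#' particle swarm and once with uniform random search at the same
#' evaluation budget (draws = particles x iterations), both maximizing
#' the same cross-validation fitness over the same fold plan. A one-sided
#' exact sign test asks whether the swarm's best fitness exceeds random
#' search's across the pairs.
#'
#' @param data same forms as in [trainPipeline()].
#' @param config a [pipelineConfig()] list; \code{nParticles * nIter}
#'   fixes the per-run budget.
#' @param seeds integer vector of paired-run seeds.
#' @param nRandom draws for each random-search run; defaults to the swarm
#'   budget (parity). Must be >= 1.
#' @return list with \code{results} (per-seed best fitness of both
#'   methods), \code{meanPSO}, \code{meanRandom}, \code{pValue} of the
#'   one-sided sign test.
#' @export
compareSearch <- function(data, config = pipelineConfig(),
                          seeds = seq_len(30L), nRandom = NULL) {
  if (!is.null(nRandom) && nRandom < 1L)
    stop("nRandom must be >= 1", call. = FALSE)
  d <- .resolveData(data)
  fm <- .featureMatrix(d$images, config)
  plan <- stratifiedKFold(d$labels, config$k, seed = config$seed)
  folds <- prepareFolds(fm$X, d$labels, plan, config$varianceTarget,
                        config$pcaScope)
  reducer <- fitReducer(fm$X)
  S <- projectPCA(fm$X, reducer, selectComponents(reducer,
                                                  config$varianceTarget))
  bounds <- rbind(config$CBounds, .sigmaBounds(config, S))
  budget <- config$nParticles * config$nIter
  if (is.null(nRandom)) nRandom <- budget
  fitness <- function(p)
    cvFitness(C = p[1], sigma = p[2], folds = folds, tol = config$tol)
  sp <- .searchSpace(bounds, fitness, config$searchScale)
  res <- t(vapply(seeds, function(s) {
    pso <- psoOptimize(sp$fitness, sp$bounds, config$nParticles,
                       config$nIter, config$w, config$c1, config$c2,
                       seed = s)
    rnd <- randomSearch(sp$fitness, sp$bounds, nDraws = nRandom,
                        seed = s + 1000000L)
    c(pso = pso$bestFitness, random = rnd$bestFitness)
  }, numeric(2)))
  results <- data.frame(seed = seeds, pso = res[, "pso"],
                        random = res[, "random"])
  wins <- sum(results$pso > results$random)
  ties <- sum(results$pso == results$random)
  nEff <- nrow(results) - ties
  p <- if (nEff > 0)
    stats::binom.test(wins, nEff, alternative = "greater")$p.value else 1
  list(results = results, meanPSO = mean(results$pso),
       meanRandom = mean(results$random), pValue = p,
       budget = c(evaluations = budget, randomDraws = nRandom))
}

#' @rdname TrainedSystem-class
#' @param object a \code{TrainedSystem}.
#' @export
setMethod("show", "TrainedSystem", function(object) {
  cat(sprintf(
    paste0("TrainedSystem: %d x %d images -> %d wavelet features -> %d PCs",
           " -> RBF KSVM\n  C* = %.4g, sigma* = %.4g, CV accuracy %.4f",
           " (%d-fold, seed %d)\n"),
    object@imageDim[1], object@imageDim[2], object@featureLength,
    object@nComponents, object@cost, object@sigma, object@cvFitness,
    object@foldPlan@k, object@config$seed))
})
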