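test_that("the 90-image study layout stratifies into 5 folds of 18", {
  labels <- rep(c(-1, 1), c(5, 85))
  plan <- stratifiedKFold(labels, k = 5, seed = 1)
  sizes <- tabulate(plan@assignments, 5)
  expect_equal(sizes, rep(18L, 5))
  # exactly one normal per fold
  for (f in 1:5)
    expect_identical(sum(labels[plan@assignments == f] == -1), 1L)
  # each fold used once for validation: 4 x 18 = 72 training per fold,
  # 360 training assignments and 90 validation in total
  trainTotal <- sum(sapply(1:5, function(f) sum(plan@assignments != f)))
  valTotal <- sum(sapply(1:5, function(f) sum(plan@assignments == f)))
  expect_identical(trainTotal, 360L)
  expect_identical(valTotal, 90L)
  # deterministic given the seed
  plan2 <- stratifiedKFold(labels, k = 5, seed = 1)
  expect_identical(plan@assignments, plan2@assignments)
})

test_that("fold assignment is a partition with graceful degradation", {
  labels <- rep(c("a", "b"), c(7, 13))
  plan <- stratifiedKFold(labels, k = 4, seed = 2)
  expect_setequal(unique(plan@assignments), 1:4)
  expect_length(plan@assignments, 20)
  expect_lte(diff(range(tabulate(plan@assignments, 4))), 1)
  # leave-one-out degenerate case
  loo <- stratifiedKFold(rep(c(-1, 1), 5), k = 10, seed = 3)
  expect_equal(sort(tabulate(loo@assignments, 10)), rep(1L, 10))
  expect_error(stratifiedKFold(rep(1, 4), k = 5), "exceed")
})

test_that("mock classifiers bracket the fitness range", {
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- sign(X[, 1]); y[y == 0] <- 1
  plan <- stratifiedKFold(y, k = 4, seed = 1)
  oracle <- structure(list(), class = "signOracle")
  alwaysRight <- function(trainX, trainY) structure(1, class = "signOracle")
  alwaysWrong <- function(trainX, trainY) structure(1, class = "signFlip")
  registerS3method("predict", "signOracle",
                   function(object, newdata, ...) {
                     p <- sign(newdata[, 1]); p[p == 0] <- 1; p
                   })
  registerS3method("predict", "signFlip",
                   function(object, newdata, ...) {
                     p <- -sign(newdata[, 1]); p[p == 0] <- 1; p
                   })
  # pcaScope global keeps the informative axis identifiable in-fold
  folds <- lapply(1:4, function(f) {
    te <- plan@assignments == f
    list(trainX = X[!te, ], trainY = y[!te], testX = X[te, ],
         testY = y[te], k = 3)
  })
  expect_equal(cvFitness(folds = folds, trainFun = alwaysRight), 1)
  expect_equal(cvFitness(folds = folds, trainFun = alwaysWrong), 0)
})

test_that("separable Gaussian classes reach high CV accuracy", {
  tr <- gaussianTrainingSet(n = 60, d = 2, sep = 4, seed = 12)
  plan <- stratifiedKFold(tr$y, k = 5, seed = 12)
  acc <- cvFitness(tr$X, tr$y, C = 10, sigma = 2, plan = plan)
  expect_gte(acc, 0.95)
})

test_that("confusion metrics reproduce printed-table arithmetic", {
  # 450 evaluations with tp=417, fn=8, fp=2, tn=23
  yTrue <- rep(c(1, -1), c(425, 25))
  yPred <- c(rep(1, 417), rep(-1, 8), rep(1, 2), rep(-1, 23))
  m <- confusionMetrics(yTrue, yPred)
  expect_equal(unname(m$confusion), c(417, 8, 2, 23))
  expect_equal(100 * m$accuracy, 97.78, tolerance = 1e-3)
  expect_equal(100 * m$sensitivity, 98.12, tolerance = 1e-3)
  expect_equal(100 * m$specificity, 92, tolerance = 1e-12)
  # second printed row: 374/51 and 11/14 give 388 successes of 450
  m2 <- confusionMetrics(rep(c(1, -1), c(425, 25)),
                         c(rep(1, 374), rep(-1, 51), rep(1, 11),
                           rep(-1, 14)))
  expect_identical(unname(m2$confusion[c("tp", "tn")]), c(374L, 14L))
  expect_equal(100 * m2$accuracy, 86.22, tolerance = 1e-2)
  expect_equal(100 * m2$sensitivity, 88.0, tolerance = 1e-2)
  expect_equal(100 * m2$specificity, 56, tolerance = 1e-12)
})

test_that("perfect, degenerate and invalid metric inputs behave", {
  p <- confusionMetrics(c(1, -1, 1), c(1, -1, 1))
  expect_equal(p$accuracy, 1)
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
  onlyPos <- confusionMetrics(c(1, 1), c(1, -1))
  expect_true(is.na(onlyPos$specificity))
  expect_equal(onlyPos$sensitivity, 0.5)
  expect_error(confusionMetrics(numeric(0), numeric(0)), "empty")
  expect_error(confusionMetrics(c(1, -1), c(1)), "equal length")
  expect_error(confusionMetrics(c(1, 2), c(1, 1)), "-1/\\+1")
})

test_that("mean-of-folds equals pooled accuracy for equal fold sizes", {
  set.seed(20)
  y <- rep(c(-1, 1), c(10, 40))
  plan <- stratifiedKFold(y, k = 5, seed = 20)
  pred <- sample(c(-1, 1), 50, replace = TRUE)
  foldAcc <- sapply(1:5, function(f) {
    idx <- plan@assignments == f
    mean(pred[idx] == y[idx])
  })
  expect_equal(mean(foldAcc), mean(pred == y))
})
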