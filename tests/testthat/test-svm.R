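test_that("kernel evaluations follow their definitions", {
  expect_equal(kernelEval(c(1, 2), c(1, 2), rbfKernel(0.7)), 1)
  # squared distance equal to sigma^2 gives exp(-1)
  expect_equal(kernelEval(0, 2, rbfKernel(2)), exp(-1))
  expect_equal(kernelEval(c(1, 2), c(3, 4), linearKernel()), 11)
  set.seed(2)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(kernelEval(a, b, rbfKernel(1.3)),
                 kernelEval(b, a, rbfKernel(1.3)))
  }
  expect_error(kernelEval(1:2, 1:3, linearKernel()), "equal dimension")
  expect_error(rbfKernel(-1), "positive")
  # Gram matrix agrees with elementwise evaluation
  X1 <- matrix(rnorm(6), 3, 2); X2 <- matrix(rnorm(4), 2, 2)
  K <- kernelMatrix(X1, X2, rbfKernel(0.9))
  expect_equal(K[2, 1], kernelEval(X1[2, ], X2[1, ], rbfKernel(0.9)))
})

test_that("the two-point problem recovers the analytic max-margin solution", {
  m <- trainKSVM(matrix(c(-1, 1), 2, 1), c(-1, 1), C = 100,
                 kernel = linearKernel())
  expect_equal(m@alphas, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(m@dualCoef), 0, tolerance = 1e-6)
  expect_equal(m@bias, 0, tolerance = 1e-6)
  expect_equal(decisionFunction(m, matrix(0)), 0, tolerance = 1e-6)
  expect_equal(decisionFunction(m, matrix(c(-1, 1), 2, 1)), c(-1, 1),
               tolerance = 1e-3)
  expect_identical(nrow(supportVectors(m)), 2L)
  # sign(0) maps to +1
  expect_equal(predict(m, matrix(0)), 1)

  # 2D: (0,0) vs (0,2) separated by the line y = 1
  m2 <- trainKSVM(rbind(c(0, 0), c(0, 2)), c(-1, 1), C = 1000,
                  kernel = linearKernel())
  expect_equal(decisionFunction(m2, rbind(c(5, 1), c(-3, 1))), c(0, 0),
               tolerance = 1e-6)
  expect_equal(decisionFunction(m2, rbind(c(0, 0), c(0, 2))), c(-1, 1),
               tolerance = 1e-3)
})

test_that("the RBF kernel separates XOR", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1, -1, 1, 1)
  m <- trainKSVM(X, y, C = 10, kernel = rbfKernel(1))
  expect_equal(predict(m, X), y)
})

test_that("solutions satisfy the KKT conditions on random problems", {
  for (s in 1:4) {
    tr <- gaussianTrainingSet(n = 30, d = 3, sep = 2, seed = s)
    for (kern in list(linearKernel(), rbfKernel(2))) {
      for (C in c(0.5, 10)) {
        m <- trainKSVM(tr$X, tr$y, C = C, kernel = kern)
        expect_lt(kktViolations(m, tr$X, tr$y), 2e-3)
        expect_true(all(m@alphas >= 0 & m@alphas <= C + 1e-8))
      }
    }
  }
})

test_that("the dual objective matches an interior-point QP oracle", {
  for (s in 1:3) {
    set.seed(s)
    n <- 50
    X <- matrix(rnorm(n * 4), n, 4)
    y <- sign(X[, 1] + 0.5 * rnorm(n)); y[y == 0] <- 1
    for (spec in list(linearKernel(), rbfKernel(3))) {
      C <- 5
      m <- trainKSVM(X, y, C = C, kernel = spec, tol = 1e-5)
      K <- kernelMatrix(X, spec = spec)
      Q <- (y %o% y) * K
      ip <- kernlab::ipop(c = matrix(-1, n), H = Q + 1e-9 * diag(n),
                          A = matrix(y, 1), b = 0, r = 0,
                          l = matrix(0, n), u = matrix(C, n),
                          sigf = 9, maxiter = 200)
      objOracle <- dualObjective(as.vector(kernlab::primal(ip)), K, y)
      expect_lt(abs(m@objective - objOracle) / abs(objOracle), 1e-5)
    }
  }
})

test_that("predictions agree with an independent SVM implementation", {
  tr <- gaussianTrainingSet(n = 60, d = 4, sep = 2.5, seed = 9)
  te <- gaussianTrainingSet(n = 40, d = 4, sep = 2.5, seed = 10)
  sg <- 3; C <- 2
  mine <- trainKSVM(tr$X, tr$y, C = C, kernel = rbfKernel(sg))
  ref <- e1071::svm(tr$X, factor(tr$y), kernel = "radial",
                    gamma = 1 / sg^2, cost = C, scale = FALSE)
  refPred <- as.numeric(as.character(predict(ref, te$X)))
  expect_equal(predict(mine, te$X), refPred)
})

test_that("training error is non-increasing in C on a fixed dataset", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- sign(X[, 1] + 0.8 * rnorm(30)); y[y == 0] <- 1
  errs <- sapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    m <- trainKSVM(X, y, C = C, kernel = rbfKernel(1.5))
    mean(predict(m, X) != y)
  })
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("invalid training inputs are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(trainKSVM(X, rep(1, 5), C = 1), "both classes")
  expect_error(trainKSVM(X, c(1, 0, 1, -1, 1), C = 1), "-1/\\+1")
  expect_error(trainKSVM(X, c(1, -1, 1, -1, 1), C = -2), "positive")
  m <- trainKSVM(X, c(1, -1, 1, -1, 1), C = 1, kernel = rbfKernel(1))
  expect_error(decisionFunction(m, matrix(0, 1, 3)), "dimension")
})
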