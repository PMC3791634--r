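test_that("Haar filters are orthonormal", {
  f <- haarFilters()
  expect_equal(sum(f$lowpass^2), 1)
  expect_equal(sum(f$highpass^2), 1)
  expect_equal(sum(f$lowpass * f$highpass), 0)
})

test_that("constant images carry no detail and gain 2 per level", {
  for (c0 in c(1, -3.5, 0.25)) {
    b <- dwt2(matrix(c0, 4, 4))
    expect_equal(b$LL, matrix(2 * c0, 2, 2))
    expect_equal(b$LH, matrix(0, 2, 2))
    expect_equal(b$HL, matrix(0, 2, 2))
    expect_equal(b$HH, matrix(0, 2, 2))
  }
})

test_that("a 2x2 block reduces to hand-computed Haar coefficients", {
  # separable Haar on [[a,b],[c,d]]: LL = (a+b+c+d)/2
  m <- matrix(c(3, -1, 7, 2), 2, 2)  # a=3, c=-1, b=7, d=2
  b <- dwt2(m)
  expect_equal(b$LL[1, 1], sum(m) / 2)
  # horizontal detail: low across columns is (a+b), (c+d); vertical high
  expect_equal(b$LH[1, 1], ((3 + 7) - (-1 + 2)) / 2)
  expect_equal(b$HL[1, 1], ((3 - 7) + (-1 - 2)) / 2)
  expect_equal(b$HH[1, 1], ((3 - 7) - (-1 - 2)) / 2)
})

test_that("single level inverts exactly on even and odd sizes", {
  for (dims in list(c(8, 8), c(6, 10), c(7, 9), c(8, 5))) {
    for (mode in c("symmetric", "periodic", "zero")) {
      x <- randomImage(dims[1], dims[2], seed = dims[1] * 10 + dims[2])
      b <- dwt2(x, mode)
      expect_equal(dim(b$LL), as.integer(ceiling(dims / 2)))
      expect_lt(max(abs(idwt2(b, dim(x)) - x)), 1e-10)
    }
  }
})

test_that("multilevel decomposition reconstructs across sizes 8-256", {
  for (n in c(8, 16, 32, 64, 128, 256)) {
    x <- randomImage(n, seed = n)
    p <- waveletDecompose(x, levels = 3)
    expect_lt(max(abs(waveletReconstruct(p) - x)), 1e-10)
  }
})

test_that("orthonormal Haar conserves energy on even sizes (Parseval)", {
  x <- randomImage(64, seed = 7)
  for (lev in 1:3) {
    p <- waveletDecompose(x, levels = lev)
    expect_lt(abs(pyramidEnergy(p) - sum(x^2)) / sum(x^2), 1e-8)
  }
  b <- dwt2(randomImage(16, seed = 3))
  expect_lt(abs(sum(unlist(lapply(b, function(m) sum(m^2)))) -
                  sum(randomImage(16, seed = 3)^2)), 1e-8)
})

test_that("the transform is linear", {
  x <- randomImage(16, seed = 1)
  y <- randomImage(16, seed = 2)
  pa <- waveletDecompose(2.5 * x - 1.5 * y, levels = 2)
  px <- waveletDecompose(x, levels = 2)
  py <- waveletDecompose(y, levels = 2)
  expect_lt(max(abs(approximation(pa) -
                      (2.5 * approximation(px) - 1.5 * approximation(py)))),
            1e-10)
  d1 <- detailBands(pa, 1)$HH
  expect_lt(max(abs(d1 - (2.5 * detailBands(px, 1)$HH -
                            1.5 * detailBands(py, 1)$HH))), 1e-10)
})

test_that("level-1 multilevel equals the single-level transform", {
  x <- randomImage(12, seed = 5)
  p <- waveletDecompose(x, levels = 1)
  b <- dwt2(x)
  expect_equal(approximation(p), b$LL)
  expect_equal(detailBands(p, 1), b[c("LH", "HL", "HH")])
})

test_that("invalid inputs are rejected", {
  expect_error(dwt2(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
  expect_error(dwt2(matrix(1, 1, 5)), "at least")
  expect_error(waveletDecompose(randomImage(8), levels = 4), "needs")
  expect_error(waveletDecompose(randomImage(8), levels = 0), ">= 1")
})

test_that("feature extraction flattens the level-3 approximation", {
  expect_length(extractFeatures(matrix(0, 256, 256)), 1024)
  expect_equal(extractFeatures(matrix(0, 256, 256)), rep(0, 1024))
  expect_length(extractFeatures(randomImage(96, 64, seed = 2)), 12 * 8)
  # row-major order: feature 1..32 is the first row of the 32x32 block
  x <- randomImage(256, seed = 9)
  A <- approximation(waveletDecompose(x, 3))
  expect_equal(extractFeatures(x)[1:32], A[1, ])
})

test_that("an impulse maps to a single coarse cell with bounded energy", {
  x <- matrix(0, 64, 64)
  x[10, 10] <- 1
  A <- approximation(waveletDecompose(x, 3))
  expect_lte(sum(A^2), sum(x^2))
  nz <- which(A != 0, arr.ind = TRUE)
  expect_equal(unname(nz), matrix(c(2L, 2L), 1))  # ceil(10/8) = 2
  expect_equal(A[2, 2], 1 / 8)
})

test_that("the approximation matches an independent wavelet library", {
  x <- randomImage(64, seed = 11)
  fx <- tempfile(fileext = ".csv")
  fo <- tempfile(fileext = ".csv")
  write.table(x, fx, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- sprintf(paste0(
    "import numpy, pywt; x = numpy.loadtxt('%s', delimiter=',');",
    "a = pywt.wavedec2(x, 'haar', mode='symmetric', level=3)[0];",
    "numpy.savetxt('%s', a, delimiter=',')"), fx, fo)
  status <- system2("python", c("-c", shQuote(script)))
  expect_identical(status, 0L)
  ref <- as.matrix(read.table(fo, sep = ","))
  mine <- approximation(waveletDecompose(x, 3))
  expect_lt(max(abs(unname(ref) - mine)), 1e-8)
})
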