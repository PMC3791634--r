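# Shared fixtures: small random matrices and toy training sets, built in
# code under fixed seeds.

randomImage <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m)
}

# total energy of a wavelet pyramid (approximation + every detail block)
pyramidEnergy <- function(p) {
  e <- sum(approximation(p)^2)
  for (j in seq_len(p@levels))
    e <- e + sum(unlist(lapply(detailBands(p, j), function(m) sum(m^2))))
  e
}

# two well-separated Gaussian clouds in `d` dimensions
gaussianTrainingSet <- function(n = 40, d = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * d), n / 2, d),
             matrix(rnorm(n / 2 * d, mean = sep), n / 2, d))
  list(X = X, y = rep(c(-1, 1), each = n / 2))
}

# brute-force dual objective of an SVM solution
dualObjective <- function(alpha, K, y) {
  av <- alpha * y
  sum(alpha) - 0.5 * sum(av * (K %*% av))
}

# KKT violation summary for a trained model evaluated on its training set;
# support vectors are matched back to training rows by exact coordinates
kktViolations <- function(model, X, y) {
  f <- decisionFunction(model, X)
  alpha <- rep(0, nrow(X))
  svKey <- apply(model@supportVectors, 1, paste, collapse = "\r")
  xKey <- apply(X, 1, paste, collapse = "\r")
  alpha[match(svKey, xKey)] <- model@alphas
  yf <- y * f
  C <- model@cost
  viol <- numeric(length(y))
  atZero <- alpha <= 1e-8 * C
  atC <- alpha >= C * (1 - 1e-8)
  free <- !atZero & !atC
  viol[atZero] <- pmax(0, 1 - yf[atZero])
  viol[free] <- abs(yf[free] - 1)
  viol[atC] <- pmax(0, yf[atC] - 1)
  max(viol)
}
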