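unitBox <- rbind(c(0, 1), c(0, 1))
sphere <- function(p) -sum(p^2)

test_that("swarm initialization is reproducible and within bounds", {
  s1 <- initSwarm(10, unitBox, seed = 3)
  s2 <- initSwarm(10, unitBox, seed = 3)
  expect_identical(s1@positions, s2@positions)
  expect_identical(s1@velocities, s2@velocities)
  expect_true(all(s1@positions >= 0 & s1@positions <= 1))
  expect_true(all(abs(s1@velocities) <= 1))
  s3 <- initSwarm(1, unitBox, seed = 1)
  expect_identical(bestPosition(s3), s3@positions[1, ])
  expect_error(initSwarm(0, unitBox), ">= 1")
  expect_error(initSwarm(3, rbind(c(1, 0))), "hi > lo")
})

test_that("a particle resting at the optimum does not move", {
  sw <- initSwarm(1, unitBox, seed = 2)
  sw@positions[1, ] <- c(0.4, 0.6)
  sw@pbestPositions[1, ] <- c(0.4, 0.6)
  sw@velocities[1, ] <- 0
  out <- psoStep(sw, sphere)
  expect_equal(out@positions[1, ], c(0.4, 0.6))
  expect_equal(out@velocities[1, ], c(0, 0))
  expect_equal(out@gbestPosition, c(0.4, 0.6))
})

test_that("the velocity update follows the stated equation exactly", {
  # trace a 3-particle swarm by replaying the documented RNG draw order:
  # per step, the r1 matrix (n x d, column-major) then the r2 matrix
  n <- 3L; d <- 2L
  w <- 0.5; c1 <- 1.2; c2 <- 1.7
  seed <- 99L
  bounds <- rbind(c(-5, 5), c(-5, 5))
  fit <- function(p) -sum((p - 1)^2)

  # pass 1: run the real swarm and record its states
  sw <- initSwarm(n, bounds, w = w, c1 = c1, c2 = c2, seed = seed)
  states <- list(list(pos = sw@positions, vel = sw@velocities))
  for (step in 1:3) {
    sw <- psoStep(sw, fit)
    states[[step + 1]] <- list(pos = sw@positions, vel = sw@velocities,
                               g = sw@gbestPosition)
  }

  # pass 2: replay the identical RNG stream by hand
  set.seed(seed)  # init consumes n*d + n*d uniforms
  lo <- matrix(bounds[, 1], n, d, byrow = TRUE)
  wd <- matrix(bounds[, 2] - bounds[, 1], n, d, byrow = TRUE)
  pos <- lo + wd * matrix(runif(n * d), n, d)
  vel <- wd * matrix(runif(n * d, -1, 1), n, d)
  expect_identical(states[[1]]$pos, pos)
  expect_identical(states[[1]]$vel, vel)

  pbest <- pos
  pfit <- rep(-Inf, n)
  for (step in 1:3) {
    f <- apply(pos, 1, fit)
    upd <- f >= pfit
    pfit[upd] <- f[upd]
    pbest[upd, ] <- pos[upd, ]
    g <- pbest[which.max(pfit), ]
    r1 <- matrix(runif(n * d), n, d)
    r2 <- matrix(runif(n * d), n, d)
    vel <- w * vel + c1 * r1 * (pbest - pos) +
      c2 * r2 * (matrix(g, n, d, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, -wd), wd)
    pos2 <- pos + vel
    outside <- pos2 < lo | pos2 > lo + wd
    vel[outside] <- -0.5 * vel[outside]   # bounce off the box
    pos <- pmin(pmax(pos2, lo), lo + wd)
    expect_identical(states[[step + 1]]$pos, pos)
    expect_identical(states[[step + 1]]$vel, vel)
    expect_identical(states[[step + 1]]$g, g)
  }
})

test_that("with w = 0 and c2 = 0 velocity points toward the personal best", {
  sw <- initSwarm(4, unitBox, w = 0, c1 = 1, c2 = 0, seed = 5)
  sw@pbestFitness <- rep(10, 4)           # pbests frozen at initial draws
  pb <- sw@pbestPositions
  p0 <- sw@positions
  out <- psoStep(sw, sphere)
  moved <- out@positions - p0
  # each movement is a non-negative elementwise scaling of (pbest - p)
  ratio <- moved / (pb - p0)
  ok <- is.nan(ratio) | (ratio >= 0 & ratio <= 1)
  expect_true(all(ok[abs(pb - p0) > 1e-12]))
})

test_that("global best fitness is monotone and dominates personal bests", {
  sw <- initSwarm(8, rbind(c(-3, 3), c(-3, 3)), seed = 11)
  prev <- -Inf
  for (i in 1:15) {
    sw <- psoStep(sw, sphere)
    expect_gte(sw@gbestFitness, prev)
    expect_equal(sw@gbestFitness, max(sw@pbestFitness))
    prev <- sw@gbestFitness
  }
})

test_that("optimization recovers a known quadratic optimum", {
  target <- c(0.3, 0.7)
  f <- function(p) -sum((p - target)^2)
  hits <- sapply(1:10, function(s)
    max(abs(psoOptimize(f, unitBox, 20, 50, seed = s)$bestPosition -
              target)) <= 1e-2)
  expect_true(all(hits))
  r <- psoOptimize(sphere, rbind(c(-2, 2), c(-2, 2)), 10, 20, seed = 3)
  expect_true(all(diff(r$history) >= 0))
  # degenerate constant fitness: any in-bounds position, no error
  rc <- psoOptimize(function(p) 1, unitBox, 5, 5, seed = 2)
  expect_true(all(rc$bestPosition >= 0 & rc$bestPosition <= 1))
  expect_equal(rc$bestFitness, 1)
})

test_that("non-finite fitness is reported with the particle index", {
  sw <- initSwarm(3, unitBox, seed = 1)
  expect_error(psoStep(sw, function(p) NaN), "particle 1")
})

test_that("random search is reproducible and beaten by the swarm", {
  f <- function(p) -sum((p - c(0.3, 0.7))^2)
  r1 <- randomSearch(f, unitBox, nDraws = 25, seed = 4)
  r2 <- randomSearch(f, unitBox, nDraws = 25, seed = 4)
  expect_identical(r1$draws, r2$draws)
  expect_identical(nrow(r1$draws), 25L)
  expect_equal(r1$bestFitness, max(r1$draws$fitness))
  single <- randomSearch(f, unitBox, nDraws = 1, seed = 9)
  expect_identical(single$bestPosition, unname(unlist(
    single$draws[1, c("x1", "x2")])))
  expect_error(randomSearch(f, unitBox, nDraws = 0), ">= 1")

  # paired comparison at equal budget on the smooth quadratic: the swarm
  # refines while uniform draws do not; one-sided sign test
  wins <- sapply(1:30, function(s) {
    pso <- psoOptimize(f, unitBox, 10, 10, seed = s)$bestFitness
    rnd <- randomSearch(f, unitBox, nDraws = 100, seed = s + 500)$bestFitness
    pso - rnd
  })
  pv <- binom.test(sum(wins > 0), sum(wins != 0),
                   alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})
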