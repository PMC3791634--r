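## Particle swarm optimizer (maximization) over a box, used to tune the
## SVM hyperparameters (C, sigma). Velocity/position update per particle i:
##   v <- w v + c1 r1 (pbest_i - p_i) + c2 r2 (gbest - p_i);  p <- p + v
## with r1, r2 drawn fresh per particle per dimension each iteration.
## RNG draw order (relied on by the single-particle trace test): within one
## step, first the full r1 matrix (n x d, column-major), then the full r2
## matrix. Positions are clamped to the bounds with the violating velocity
## component zeroed; |v| is clamped to the box width.

.checkBounds <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(!is.finite(bounds)) ||
      any(bounds[, 2] <= bounds[, 1]))
    stop("bounds must be a d x 2 matrix with hi > lo", call. = FALSE)
  bounds
}

#' Initialize a particle swarm
#'
#' Positions are drawn uniformly over the box, velocities uniformly over
#' +/- the box width; personal bests start at the initial positions with
#' fitness -Inf (the first [psoStep()] evaluates them).
#'
#' @param nParticles swarm size (>= 1).
#' @param bounds d x 2 matrix of per-dimension (lo, hi) limits.
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param seed optional integer seed for reproducibility.
#' @return a [Swarm-class].
#' @export
initSwarm <- function(nParticles, bounds, w = 0.7298, c1 = 1.49445,
                      c2 = 1.49445, seed = NULL) {
  if (nParticles < 1L) stop("nParticles must be >= 1", call. = FALSE)
  bounds <- .checkBounds(bounds)
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(bounds)
  lo <- matrix(bounds[, 1], nParticles, d, byrow = TRUE)
  hi <- matrix(bounds[, 2], nParticles, d, byrow = TRUE)
  pos <- lo + (hi - lo) * matrix(runif(nParticles * d), nParticles, d)
  vel <- (hi - lo) * matrix(runif(nParticles * d, -1, 1), nParticles, d)
  new("Swarm", positions = pos, velocities = vel,
      pbestPositions = pos,
      pbestFitness = rep(-Inf, nParticles),
      gbestPosition = pos[1L, ], gbestFitness = -Inf,
      w = w, c1 = c1, c2 = c2, bounds = bounds, iteration = 0L)
}

#' Advance the swarm by one iteration
#'
#' Evaluates the fitness at every current position, updates personal and
#' global bests (best = maximal fitness), then applies the velocity and
#' position update. A particle sitting at its own personal best, which is
#' also the global best, with zero velocity does not move.
#'
#' @param swarm a [Swarm-class].
#' @param fitness function taking a position vector, returning a finite
#'   scalar.
#' @return the updated [Swarm-class].
#' @export
psoStep <- function(swarm, fitness) {
  stopifnot(is(swarm, "Swarm"))
  n <- nrow(swarm@positions)
  d <- ncol(swarm@positions)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    fi <- fitness(swarm@positions[i, ])
    if (!is.finite(fi))
      stop(sprintf("fitness returned a non-finite value for particle %d", i),
           call. = FALSE)
    fit[i] <- fi
  }
  # ties accepted (>=): on plateaus of a quantized fitness the personal
  # best tracks the particle's latest equally-good position, so the swarm
  # keeps drifting instead of anchoring to its initial draw
  improved <- fit >= swarm@pbestFitness
  swarm@pbestFitness[improved] <- fit[improved]
  swarm@pbestPositions[improved, ] <- swarm@positions[improved, ]
  best <- which.max(swarm@pbestFitness)
  swarm@gbestFitness <- swarm@pbestFitness[best]
  swarm@gbestPosition <- swarm@pbestPositions[best, ]

  r1 <- matrix(runif(n * d), n, d)
  r2 <- matrix(runif(n * d), n, d)
  G <- matrix(swarm@gbestPosition, n, d, byrow = TRUE)
  v <- swarm@w * swarm@velocities +
    swarm@c1 * r1 * (swarm@pbestPositions - swarm@positions) +
    swarm@c2 * r2 * (G - swarm@positions)
  width <- matrix(swarm@bounds[, 2] - swarm@bounds[, 1], n, d, byrow = TRUE)
  v <- pmin(pmax(v, -width), width)
  p <- swarm@positions + v
  lo <- matrix(swarm@bounds[, 1], n, d, byrow = TRUE)
  hi <- matrix(swarm@bounds[, 2], n, d, byrow = TRUE)
  outside <- p < lo | p > hi
  # bounce back: reflect the violating velocity component with damping.
  # (Zeroing it instead makes a boundary-attracting fitness surface an
  # absorbing state for the whole swarm, which then stagnates there.)
  v[outside] <- -0.5 * v[outside]
  p <- pmin(pmax(p, lo), hi)          # clamp to the box
  swarm@velocities <- v
  swarm@positions <- p
  swarm@iteration <- swarm@iteration + 1L
  swarm
}

#' Particle swarm maximization over a box
#'
#' @param fitness function of a position vector returning a finite scalar
#'   to maximize.
#' @param bounds d x 2 matrix of per-dimension limits.
#' @param nParticles swarm size; default 20.
#' @param nIter iteration budget; default 50.
#' @param w inertia weight: either a constant, or a length-2 vector
#'   \code{(w_start, w_end)} interpolated linearly over the iterations —
#'   the classic decaying schedule that starts explorative and ends
#'   exploitative.
#' @inheritParams initSwarm
#' @return list with \code{bestPosition}, \code{bestFitness},
#'   \code{history} (per-iteration global best, non-decreasing) and the
#'   final \code{swarm}.
#' @examples
#' f <- function(p) -sum((p - c(0.3, 0.7))^2)
#' r <- psoOptimize(f, rbind(c(0, 1), c(0, 1)), seed = 1)
#' r$bestPosition  # close to (0.3, 0.7)
#' @export
psoOptimize <- function(fitness, bounds, nParticles = 20L, nIter = 50L,
                        w = c(0.9, 0.4), c1 = 1.49445, c2 = 1.49445,
                        seed = NULL) {
  if (nIter < 1L) stop("nIter must be >= 1", call. = FALSE)
  wSched <- if (length(w) == 2L) {
    if (nIter == 1L) w[1] else seq(w[1], w[2], length.out = nIter)
  } else rep(w[1], nIter)
  swarm <- initSwarm(nParticles, bounds, wSched[1], c1, c2, seed)
  history <- numeric(nIter)
  for (t in seq_len(nIter)) {
    swarm@w <- wSched[t]
    swarm <- psoStep(swarm, fitness)
    history[t] <- swarm@gbestFitness
  }
  list(bestPosition = swarm@gbestPosition,
       bestFitness = swarm@gbestFitness,
       history = history, swarm = swarm)
}

#' Uniform random search over a box
#'
#' The random-selection baseline the swarm search is compared against:
#' \code{nDraws} positions drawn uniformly over the bounds, keeping the
#' best by fitness.
#'
#' @inheritParams psoOptimize
#' @param nDraws number of draws (>= 1).
#' @return list with \code{bestPosition}, \code{bestFitness}, and
#'   \code{draws} (a data.frame of all positions and their fitness).
#' @export
randomSearch <- function(fitness, bounds, nDraws, seed = NULL) {
  if (nDraws < 1L) stop("nDraws must be >= 1", call. = FALSE)
  bounds <- .checkBounds(bounds)
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(bounds)
  pos <- matrix(bounds[, 1], nDraws, d, byrow = TRUE) +
    matrix(bounds[, 2] - bounds[, 1], nDraws, d, byrow = TRUE) *
      matrix(runif(nDraws * d), nDraws, d)
  fit <- apply(pos, 1L, fitness)
  best <- which.max(fit)
  draws <- as.data.frame(pos)
  names(draws) <- paste0("x", seq_len(d))
  draws$fitness <- fit
  list(bestPosition = pos[best, ], bestFitness = fit[best], draws = draws)
}

#' @describeIn Swarm-class best position found so far.
#' @param object a \code{Swarm}.
#' @export
setGeneric("bestPosition", function(object) standardGeneric("bestPosition"))

#' @rdname Swarm-class
#' @export
setMethod("bestPosition", "Swarm", function(object) object@gbestPosition)

#' @rdname Swarm-class
#' @export
setMethod("show", "Swarm", function(object) {
  cat(sprintf(
    "Swarm: %d particles in %d dimensions, iteration %d\n  w = %.4g, c1 = %.4g, c2 = %.4g, gbest fitness %.6g\n",
    nrow(object@positions), ncol(object@positions), object@iteration,
    object@w, object@c1, object@c2, object@gbestFitness))
})
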