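## Decimated 2D Haar DWT with boundary extension for odd-sized inputs.
## Filters are the orthonormal pair g = (1,1)/sqrt(2), h = (1,-1)/sqrt(2),
## so one 2D level conserves energy exactly on even-sized inputs (Parseval).

#' Orthonormal Haar filter pair
#'
#' @return list with \code{lowpass} \eqn{g=(1,1)/\sqrt2} and \code{highpass}
#'   \eqn{h=(1,-1)/\sqrt2}; \eqn{\|g\|=\|h\|=1}, \eqn{g\cdot h=0}.
#' @examples
#' f <- haarFilters()
#' sum(f$lowpass^2)           # 1
#' sum(f$lowpass * f$highpass) # 0
#' @export
haarFilters <- function() {
  s <- 1 / sqrt(2)
  list(lowpass = c(s, s), highpass = c(s, -s))
}

.checkImage <- function(x, minDim = 2L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(x)))
    stop("image contains non-finite values", call. = FALSE)
  if (nrow(x) < minDim || ncol(x) < minDim)
    stop(sprintf("image dimensions must be at least %d x %d", minDim, minDim),
         call. = FALSE)
  invisible(x)
}

## Extend a matrix by one trailing row/column when the length is odd.
.padAxis <- function(x, margin, mode) {
  n <- dim(x)[margin]
  if (n %% 2L == 0L) return(x)
  extra <- switch(mode,
    symmetric = if (margin == 1L) x[n, , drop = FALSE]
                else x[, n, drop = FALSE],
    periodic  = if (margin == 1L) x[1L, , drop = FALSE]
                else x[, 1L, drop = FALSE],
    zero      = if (margin == 1L) matrix(0, 1L, ncol(x))
                else matrix(0, nrow(x), 1L),
    stop("unknown boundary mode: ", mode, call. = FALSE)
  )
  if (margin == 1L) rbind(x, extra) else cbind(x, extra)
}

## Pairwise analysis step along rows (margin = 1) or columns (margin = 2).
.dwtAxis <- function(x, margin, mode) {
  x <- .padAxis(x, margin, mode)
  s <- 1 / sqrt(2)
  if (margin == 1L) {
    odd <- seq(1L, nrow(x), by = 2L)
    a <- (x[odd, , drop = FALSE] + x[odd + 1L, , drop = FALSE]) * s
    d <- (x[odd, , drop = FALSE] - x[odd + 1L, , drop = FALSE]) * s
  } else {
    odd <- seq(1L, ncol(x), by = 2L)
    a <- (x[, odd, drop = FALSE] + x[, odd + 1L, drop = FALSE]) * s
    d <- (x[, odd, drop = FALSE] - x[, odd + 1L, drop = FALSE]) * s
  }
  list(a = a, d = d)
}

.idwtAxis <- function(a, d, margin, outLen) {
  s <- 1 / sqrt(2)
  if (margin == 1L) {
    n2 <- nrow(a)
    out <- matrix(0, 2L * n2, ncol(a))
    odd <- seq(1L, 2L * n2, by = 2L)
    out[odd, ] <- (a + d) * s
    out[odd + 1L, ] <- (a - d) * s
    out[seq_len(outLen), , drop = FALSE]
  } else {
    n2 <- ncol(a)
    out <- matrix(0, nrow(a), 2L * n2)
    odd <- seq(1L, 2L * n2, by = 2L)
    out[, odd] <- (a + d) * s
    out[, odd + 1L] <- (a - d) * s
    out[, seq_len(outLen), drop = FALSE]
  }
}

#' One level of the 2D Haar DWT
#'
#' Filters along rows first (within each row, i.e. across columns), then
#' along columns, downsampling by two on each axis. Subband naming follows
#' the filter order \emph{(horizontal, vertical)}: \code{LH} is low-pass
#' horizontal / high-pass vertical, \code{HL} the converse, \code{HH}
#' high-pass both ways. Odd axis lengths are extended by one sample
#' according to \code{boundaryMode} before filtering, giving
#' ceiling-halved subbands.
#'
#' @param image numeric matrix, all values finite, dimensions >= 2.
#' @param boundaryMode \code{"symmetric"} (repeat the edge sample),
#'   \code{"periodic"} (wrap) or \code{"zero"}.
#' @return list of matrices \code{LL}, \code{LH}, \code{HL}, \code{HH},
#'   each of dimension \code{ceiling(dim(image)/2)}.
#' @examples
#' b <- dwt2(matrix(1, 4, 4))
#' b$LL  # all 2: the 2D Haar approximation gain is 2 per level
#' @export
dwt2 <- function(image, boundaryMode = c("symmetric", "periodic", "zero")) {
  boundaryMode <- match.arg(boundaryMode)
  .checkImage(image)
  h <- .dwtAxis(image, 2L, boundaryMode)       # horizontal pass
  lo <- .dwtAxis(h$a, 1L, boundaryMode)        # vertical pass of L
  hi <- .dwtAxis(h$d, 1L, boundaryMode)        # vertical pass of H
  list(LL = lo$a, LH = lo$d, HL = hi$a, HH = hi$d)
}

#' Invert one level of the 2D Haar DWT
#'
#' Exact inverse of [dwt2()] given the original image dimensions (needed to
#' drop the extension sample when an axis was odd).
#'
#' @param bands list with \code{LL}, \code{LH}, \code{HL}, \code{HH}.
#' @param outDim integer length-2 vector, the original \code{dim(image)}.
#' @return reconstructed matrix of dimension \code{outDim}.
#' @export
idwt2 <- function(bands, outDim) {
  padDim <- outDim + outDim %% 2L
  L <- .idwtAxis(bands$LL, bands$LH, 1L, padDim[1])
  H <- .idwtAxis(bands$HL, bands$HH, 1L, padDim[1])
  x <- .idwtAxis(L, H, 2L, padDim[2])
  x[seq_len(outDim[1]), seq_len(outDim[2]), drop = FALSE]
}

#' Multilevel 2D Haar decomposition
#'
#' Applies [dwt2()] recursively to the running approximation (LL) subband,
#' keeping every level's detail blocks.
#'
#' @inheritParams dwt2
#' @param levels number of levels J >= 1; requires
#'   \code{min(dim(image)) / 2^levels >= 1}.
#' @return a [WaveletPyramid-class].
#' @examples
#' p <- waveletDecompose(matrix(rnorm(64^2), 64, 64), levels = 3)
#' dim(approximation(p))  # 8 x 8
#' @export
waveletDecompose <- function(image, levels = 3L,
                             boundaryMode = c("symmetric", "periodic",
                                              "zero")) {
  boundaryMode <- match.arg(boundaryMode)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  .checkImage(image)
  if (min(dim(image)) < 2L^levels)
    stop(sprintf("a %d-level transform needs min(dim) >= %d", levels,
                 2L^levels), call. = FALSE)
  details <- vector("list", levels)
  a <- image
  for (j in seq_len(levels)) {
    b <- dwt2(a, boundaryMode)
    details[[j]] <- b[c("LH", "HL", "HH")]
    a <- b$LL
  }
  new("WaveletPyramid", levels = levels, approximation = a,
      details = details, boundaryMode = boundaryMode,
      inputDim = as.integer(dim(image)))
}

#' Reconstruct an image from a wavelet pyramid
#'
#' @param pyramid a [WaveletPyramid-class].
#' @return matrix with the original image dimensions; for all boundary modes
#'   the round trip through [waveletDecompose()] is exact to numerical
#'   precision.
#' @export
waveletReconstruct <- function(pyramid) {
  stopifnot(is(pyramid, "WaveletPyramid"))
  dims <- vector("list", pyramid@levels)
  d <- pyramid@inputDim
  for (j in seq_len(pyramid@levels)) {
    dims[[j]] <- d
    d <- as.integer(ceiling(d / 2))
  }
  a <- pyramid@approximation
  for (j in rev(seq_len(pyramid@levels))) {
    bands <- pyramid@details[[j]]
    bands$LL <- a
    a <- idwt2(bands, dims[[j]])
  }
  a
}

#' Wavelet approximation features
#'
#' Flattens the level-\code{levels} approximation block row-major into the
#' feature vector used downstream: a 256 x 256 image at 3 levels yields the
#' 32 x 32 = 1024 approximation coefficients, a 64-fold reduction from the
#' 65536 raw pixels.
#'
#' @inheritParams waveletDecompose
#' @return numeric feature vector of length
#'   \code{ceiling(nrow/2^levels) * ceiling(ncol/2^levels)}.
#' @examples
#' length(extractFeatures(matrix(0, 256, 256)))  # 1024
#' @export
extractFeatures <- function(image, levels = 3L,
                            boundaryMode = c("symmetric", "periodic",
                                             "zero")) {
  boundaryMode <- match.arg(boundaryMode)
  p <- waveletDecompose(image, levels, boundaryMode)
  as.vector(t(p@approximation))
}

#' @describeIn WaveletPyramid-class final approximation (LL) block.
#' @param object,x a \code{WaveletPyramid}.
#' @export
setGeneric("approximation", function(object) standardGeneric("approximation"))

#' @rdname WaveletPyramid-class
#' @export
setMethod("approximation", "WaveletPyramid", function(object)
  object@approximation)

#' @describeIn WaveletPyramid-class detail blocks of one level.
#' @param level level index, 1 = finest.
#' @export
setGeneric("detailBands", function(object, level)
  standardGeneric("detailBands"))

#' @rdname WaveletPyramid-class
#' @export
setMethod("detailBands", "WaveletPyramid", function(object, level)
  object@details[[level]])

#' @rdname WaveletPyramid-class
#' @export
setMethod("show", "WaveletPyramid", function(object) {
  cat(sprintf(
    "WaveletPyramid: %d-level Haar, %s boundary\n  input %d x %d -> approximation %d x %d\n",
    object@levels, object@boundaryMode,
    object@inputDim[1], object@inputDim[2],
    nrow(object@approximation), ncol(object@approximation)))
})
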