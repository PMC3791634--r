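## Seeded two-class brain-phantom generator. Phantoms are deliberately
## minimal: a smooth elliptical "brain" (radial intensity profile, bright
## rim, dark ventricle shapes, low-frequency texture) plus Gaussian pixel
## noise, where the abnormal class adds hyperintense lesion disks inside
## the brain mask. The contract is statistical — a controllable, localized
## class difference — not anatomical realism.

#' Construct a phantom specification
#'
#' Defaults emulate a 90-slice study set: 256 x 256 images, 5 normal and
#' 85 abnormal, 1-4 lesions of radius 5-20 px per abnormal image with
#' additive contrast 0.5 on the [0,1] intensity scale, and pixel noise of
#' standard deviation 0.05.
#'
#' @param size image side in pixels.
#' @param nNormal,nAbnormal class counts.
#' @param lesionCountRange integer (min, max) lesions per abnormal image.
#' @param lesionRadiusRange (min, max) lesion radius in pixels.
#' @param lesionContrast additive lesion intensity; 0 removes the class
#'   difference entirely.
#' @param noiseSd Gaussian pixel-noise standard deviation.
#' @param seed integer seed used by [generatePhantomDataset()].
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(size = 256L, nNormal = 5L, nAbnormal = 85L,
                        lesionCountRange = c(1L, 4L),
                        lesionRadiusRange = c(5, 20),
                        lesionContrast = 0.5, noiseSd = 0.05, seed = 1L) {
  new("PhantomSpec", size = as.integer(size),
      nNormal = as.integer(nNormal), nAbnormal = as.integer(nAbnormal),
      lesionCountRange = as.integer(lesionCountRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      lesionContrast = as.numeric(lesionContrast),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Generate one phantom image
#'
#' Draws from the current RNG stream (seed it with \code{set.seed()} for a
#' reproducible image; [generatePhantomDataset()] does this once per
#' dataset). Base image: elliptical brain mask with a quadratic radial
#' intensity profile, a bright rim, two dark ventricle shapes and smooth
#' random low-frequency texture; Gaussian noise is added before lesion
#' placement so that a zero-contrast "abnormal" image with zero noise is
#' identical to its normal counterpart. Abnormal images add
#' \code{lesionContrast} on hard disks placed fully inside the mask.
#' Values are clipped to [0, 1].
#'
#' @param spec a [PhantomSpec-class].
#' @param abnormal logical; add lesions?
#' @return \code{size} x \code{size} intensity matrix in [0, 1].
#' @export
generatePhantom <- function(spec, abnormal = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  s <- spec@size
  ax <- (2 * seq_len(s) - s - 1) / s            # [-1, 1] pixel centers
  u <- matrix(ax, s, s, byrow = TRUE)           # horizontal coordinate
  v <- matrix(ax, s, s)                         # vertical coordinate
  re <- sqrt((u / 0.78)^2 + (v / 0.92)^2)       # elliptical radius
  mask <- re <= 1

  img <- matrix(0.02, s, s)
  img[mask] <- 0.42 * (1 - 0.3 * re[mask]^2)
  img <- img + 0.22 * exp(-((re - 0.96) / 0.045)^2)        # rim
  vent <- 0.20 * (exp(-(((u - 0.16) / 0.10)^2 + ((v + 0.08) / 0.24)^2)) +
                  exp(-(((u + 0.16) / 0.10)^2 + ((v + 0.08) / 0.24)^2)))
  img[mask] <- img[mask] - vent[mask]

  # per-image intensity inhomogeneity of a few percent: small relative to
  # lesion contrast, since lesions are hyperintense relative to tissue
  # variability
  nWaves <- 5L
  amp <- runif(nWaves, 0.001, 0.005)
  fu <- runif(nWaves, 0.5, 2.5)
  fv <- runif(nWaves, 0.5, 2.5)
  ph <- runif(nWaves, 0, 2 * pi)
  tex <- matrix(0, s, s)
  for (i in seq_len(nWaves))
    tex <- tex + amp[i] * cos(2 * pi * (fu[i] * u + fv[i] * v) + ph[i])
  img[mask] <- img[mask] + tex[mask]

  # noise is confined to the head: display-processed atlas slices have a
  # clean black air background
  if (spec@noiseSd > 0) {
    head <- re <= 1.05                # brain plus skull rim
    img[head] <- img[head] + rnorm(sum(head), 0, spec@noiseSd)
  }

  if (abnormal) {
    nles <- sample(seq(spec@lesionCountRange[1], spec@lesionCountRange[2]),
                   1L)
    px <- (u + 1) * s / 2                        # pixel-unit coordinates
    py <- (v + 1) * s / 2
    for (l in seq_len(nles)) {
      r <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
      ru <- 2 * r / s
      for (try in 1:200) {                       # place fully inside mask
        uc <- runif(1, -1, 1)
        vc <- runif(1, -1, 1)
        if (sqrt(((abs(uc) + ru) / 0.78)^2 +
                 ((abs(vc) + ru) / 0.92)^2) <= 0.92) break
      }
      d2 <- (px - (uc + 1) * s / 2)^2 + (py - (vc + 1) * s / 2)^2
      img <- img + spec@lesionContrast * (d2 <= r^2)
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a labelled phantom dataset
#'
#' Seeds the RNG from \code{spec@seed}, generates \code{nNormal} normal
#' (label -1) then \code{nAbnormal} abnormal (label +1) phantoms, and
#' optionally writes them as PNG files plus a \code{manifest.csv}
#' (columns \code{path}, \code{label}).
#'
#' @param spec a [PhantomSpec-class].
#' @param dir optional output directory; created if missing.
#' @return list with \code{images} (list of matrices), \code{labels}
#'   (-1/+1 vector), \code{manifest} (data.frame), \code{spec}.
#' @examples
#' ds <- generatePhantomDataset(phantomSpec(size = 64, nNormal = 2,
#'                                          nAbnormal = 4))
#' table(ds$labels)
#' @export
generatePhantomDataset <- function(spec, dir = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  n <- spec@nNormal + spec@nAbnormal
  labels <- rep(c(-1, 1), c(spec@nNormal, spec@nAbnormal))
  images <- vector("list", n)
  for (i in seq_len(n))
    images[[i]] <- generatePhantom(spec, abnormal = labels[i] > 0)
  paths <- sprintf("img_%03d_%s.png", seq_len(n),
                   ifelse(labels > 0, "abnormal", "normal"))
  manifest <- data.frame(path = paths, label = labels,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n))
      png::writePNG(images[[i]], file.path(dir, paths[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    manifest$path <- file.path(dir, paths)
  }
  list(images = images, labels = labels, manifest = manifest, spec = spec)
}

#' @rdname PhantomSpec-class
#' @param object a \code{PhantomSpec}.
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d, %d normal + %d abnormal\n  lesions %d-%d of radius %.3g-%.3g px, contrast %.3g, noise sd %.3g, seed %d\n",
    object@size, object@size, object@nNormal, object@nAbnormal,
    object@lesionCountRange[1], object@lesionCountRange[2],
    object@lesionRadiusRange[1], object@lesionRadiusRange[2],
    object@lesionContrast, object@noiseSd, object@seed))
})
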