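## Raster loading, manifest parsing and model (de)serialization.
## Models are stored as a versioned JSON bundle with full-precision
## numbers, so a save/load round trip reproduces decision values exactly.

#' Load a grayscale image
#'
#' Reads PNG or TIFF rasters (any bit depth the readers support) or a
#' plain-text numeric matrix (whitespace- or comma-separated). Intensities
#' are returned on a [0, 1] scale: PNG/TIFF readers already deliver this
#' (an 8-bit 255 becomes 1.0); text matrices with values above 1 are
#' divided by their maximum. Color images are converted to luminance with
#' Rec. 601 weights (0.299, 0.587, 0.114); an alpha channel is discarded.
#'
#' @param path image file path.
#' @return numeric matrix in [0, 1].
#' @export
loadImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("failed to decode ", path, ": ",
                                            conditionMessage(e),
                                            call. = FALSE)),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("failed to decode ", path, ": ",
                                             conditionMessage(e),
                                             call. = FALSE)),
    txt = ,
    csv = ,
    dat = {
      m <- as.matrix(utils::read.table(path, header = FALSE,
                                       sep = if (ext == "csv") "," else ""))
      storage.mode(m) <- "double"
      if (any(!is.finite(m)))
        stop("non-finite values in ", path, call. = FALSE)
      if (max(m) > 1) m <- m / max(m)
      m
    },
    stop("unsupported image format: .", ext, " (", path, ")", call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  unname(as.matrix(img))
}

#' Read a dataset manifest
#'
#' CSV with columns \code{path} and \code{label}; labels may be -1/+1 or
#' the strings \code{normal}/\code{abnormal}. Relative paths are resolved
#' against the manifest's directory. Duplicate or missing files are
#' errors.
#'
#' @param path manifest CSV path.
#' @return data.frame with \code{path} (absolute) and numeric \code{label}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    stop("cannot read manifest: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have 'path' and 'label' columns", call. = FALSE)
  lab <- m$label
  if (is.character(lab)) {
    lab <- c(normal = -1, abnormal = 1)[tolower(trimws(lab))]
  }
  lab <- as.numeric(lab)
  if (any(is.na(lab)) || !all(lab %in% c(-1, 1)))
    stop("labels must be -1/+1 or normal/abnormal", call. = FALSE)
  base <- dirname(normalizePath(path))
  full <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                 file.path(base, m$path))
  if (anyDuplicated(full))
    stop("duplicate paths in manifest", call. = FALSE)
  missing <- !file.exists(full)
  if (any(missing))
    stop("manifest entries not found: ",
         paste(utils::head(full[missing], 3), collapse = ", "),
         call. = FALSE)
  data.frame(path = full, label = lab, stringsAsFactors = FALSE)
}

.MODEL_FORMAT <- "1.0"

.packMatrix <- function(m) list(dim = dim(m), data = as.vector(m))
.unpackMatrix <- function(p)
  matrix(unlist(p$data), unlist(p$dim)[1], unlist(p$dim)[2])

#' Save / load a trained system
#'
#' The model file is a versioned JSON bundle holding the reducer, the SVM,
#' the tuned hyperparameters, the fold plan and the full configuration.
#' Numbers are written at full precision, so reloaded models reproduce
#' decision values bit for bit. Unknown extra fields in a file with a
#' compatible major version are ignored with a warning; a different major
#' version is an error.
#'
#' @param system a [TrainedSystem-class].
#' @param path destination / source file.
#' @return \code{loadModel} returns the [TrainedSystem-class];
#'   \code{saveModel} returns \code{path} invisibly.
#' @export
saveModel <- function(system, path) {
  stopifnot(is(system, "TrainedSystem"))
  bundle <- list(
    format = .MODEL_FORMAT,
    package = "brainKSVM",
    reducer = list(
      center = system@reducer@center, scale = system@reducer@scale,
      rotation = .packMatrix(system@reducer@rotation),
      sdev = system@reducer@sdev,
      varianceRatio = system@reducer@varianceRatio,
      nSamples = system@reducer@nSamples),
    nComponents = system@nComponents,
    svm = list(
      supportVectors = .packMatrix(system@svm@supportVectors),
      dualCoef = system@svm@dualCoef, alphas = system@svm@alphas,
      bias = system@svm@bias, C = system@svm@cost,
      objective = system@svm@objective,
      kernel = list(kind = system@svm@kernel@kind,
                    sigma = system@svm@kernel@sigma)),
    C = system@cost, sigma = system@sigma, cvFitness = system@cvFitness,
    history = system@history,
    foldPlan = list(k = system@foldPlan@k,
                    assignments = system@foldPlan@assignments,
                    seed = system@foldPlan@seed),
    config = system@config,
    imageDim = system@imageDim, featureLength = system@featureLength)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path))
    stop("cannot read model: ", path, call. = FALSE)
  bundle <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("corrupted model file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(bundle$format) || is.null(bundle$package))
    stop("not a brainKSVM model file: ", path, call. = FALSE)
  major <- function(v) strsplit(as.character(v), ".", fixed = TRUE)[[1]][1]
  if (major(bundle$format) != major(.MODEL_FORMAT))
    stop(sprintf("incompatible model format %s (this package reads %s)",
                 bundle$format, .MODEL_FORMAT), call. = FALSE)
  known <- c("format", "package", "reducer", "nComponents", "svm", "C",
             "sigma", "cvFitness", "history", "foldPlan", "config",
             "imageDim", "featureLength")
  extra <- setdiff(names(bundle), known)
  if (length(extra))
    warning("ignoring unknown model fields: ", paste(extra, collapse = ", "))
  reducer <- new("PCAModel",
    center = as.numeric(bundle$reducer$center),
    scale = as.numeric(bundle$reducer$scale),
    rotation = .unpackMatrix(bundle$reducer$rotation),
    sdev = as.numeric(bundle$reducer$sdev),
    varianceRatio = as.numeric(bundle$reducer$varianceRatio),
    nSamples = as.integer(bundle$reducer$nSamples))
  kernel <- new("KernelSpec", kind = bundle$svm$kernel$kind,
                sigma = as.numeric(bundle$svm$kernel$sigma))
  svm <- new("KSVMModel",
    supportVectors = .unpackMatrix(bundle$svm$supportVectors),
    dualCoef = as.numeric(bundle$svm$dualCoef),
    alphas = as.numeric(bundle$svm$alphas),
    bias = as.numeric(bundle$svm$bias), kernel = kernel,
    cost = as.numeric(bundle$svm$C),
    objective = as.numeric(bundle$svm$objective))
  plan <- new("FoldPlan", k = as.integer(bundle$foldPlan$k),
              assignments = as.integer(bundle$foldPlan$assignments),
              seed = as.integer(bundle$foldPlan$seed))
  new("TrainedSystem", reducer = reducer,
      nComponents = as.integer(bundle$nComponents), svm = svm,
      cost = as.numeric(bundle$C), sigma = as.numeric(bundle$sigma),
      cvFitness = as.numeric(bundle$cvFitness),
      history = as.numeric(bundle$history), foldPlan = plan,
      config = as.list(bundle$config),
      imageDim = as.integer(bundle$imageDim),
      featureLength = as.integer(bundle$featureLength))
}
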