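#' @import methods
#' @importFrom stats sd median quantile rnorm runif fft cor
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @useDynLib cryosift, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' ClassAverageStack: a stack of square 2D class-average images
#'
#' Container for a stack of aligned-and-averaged particle projections
#' ("2D class averages") that share a single pixel size. This is the unit
#' everything downstream operates on: preprocessing, mass estimation and
#' CNN quality scoring all consume one stack at a time.
#'
#' @slot images numeric array of dimension \code{side x side x n}; pixel
#'   values are in arbitrary (platform-dependent) intensity units.
#' @slot pixelSize numeric(1), Angstrom per pixel, strictly positive.
#' @slot sourceId character(1) free-text provenance tag (e.g. the file the
#'   stack came from).
#'
#' @seealso [classAverageStack()], [readClassStack()], [writeClassStack()]
#' @export
setClass("ClassAverageStack",
  representation(
    images = "array",
    pixelSize = "numeric",
    sourceId = "character"
  )
)

setValidity("ClassAverageStack", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3L) {
    msg <- c(msg, "'images' must be a 3D array (side x side x n)")
  } else {
    if (d[1] != d[2]) msg <- c(msg, "images must be square (side x side)")
    if (d[1] < 1L) msg <- c(msg, "image side must be >= 1")
    if (d[3] < 1L) msg <- c(msg, "stack must contain at least one image")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    msg <- c(msg, "'pixelSize' must be a single finite positive number")
  }
  if (length(object@sourceId) != 1L) {
    msg <- c(msg, "'sourceId' must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClassAverageStack
#'
#' @param images either a 3D array (side x side x n) or a list of square
#'   numeric matrices sharing one side length.
#' @param pixelSize pixel size in Angstrom per pixel (> 0).
#' @param sourceId free-text provenance tag.
#' @return A [ClassAverageStack-class] object.
#' @examples
#' st <- classAverageStack(list(matrix(0, 32, 32)), pixelSize = 1.1)
#' nClasses(st)
#' @export
classAverageStack <- function(images, pixelSize, sourceId = "memory") {
  if (is.list(images)) {
    sides <- vapply(images, function(m) {
      if (!is.matrix(m) || nrow(m) != ncol(m)) {
        stop("all images must be square matrices", call. = FALSE)
      }
      nrow(m)
    }, integer(1))
    if (length(unique(sides)) > 1L) {
      stop("all images in a stack must share one side length", call. = FALSE)
    }
    arr <- array(unlist(images, use.names = FALSE),
                 dim = c(sides[1], sides[1], length(images)))
  } else {
    arr <- images
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  }
  storage.mode(arr) <- "double"
  new("ClassAverageStack", images = arr, pixelSize = as.numeric(pixelSize),
      sourceId = as.character(sourceId))
}

#' @rdname classAverageStack
#' @param object,x a \code{ClassAverageStack}.
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))

#' @rdname classAverageStack
#' @export
setMethod("nClasses", "ClassAverageStack", function(object) {
  dim(object@images)[3]
})

#' @rdname classAverageStack
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname classAverageStack
#' @export
setMethod("pixelSize", "ClassAverageStack", function(object) object@pixelSize)

#' @rdname classAverageStack
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @rdname classAverageStack
#' @export
setMethod("sourceId", "ClassAverageStack", function(object) object@sourceId)

#' @rdname classAverageStack
#' @param i class index (1-based).
#' @export
classImage <- function(x, i) {
  stopifnot(is(x, "ClassAverageStack"))
  i <- as.integer(i)
  if (i < 1L || i > nClasses(x)) stop("class index out of range")
  x@images[, , i]
}

#' @exportMethod show
setMethod("show", "ClassAverageStack", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "ClassAverageStack: %d classes, %d x %d px, %.4g A/px (source: %s)\n",
    d[3], d[1], d[2], object@pixelSize, object@sourceId))
})

#' CanvasImage: a class average mapped onto the fixed 210 x 210 model canvas
#'
#' The CNN consumes a fixed 210 x 210 canvas. Images larger than the canvas
#' are Fourier down-sampled (central low-frequency block of the spectrum is
#' retained); smaller images are standardized and zero-padded; 210 px images
#' are standardized in place. See [resampleToCanvas()].
#'
#' @slot pixels 210 x 210 numeric matrix.
#' @slot originSide integer(1), side of the original image in px.
#' @slot method one of \code{"identity"}, \code{"fourier_downsample"},
#'   \code{"zero_pad"}.
#' @export
setClass("CanvasImage",
  representation(pixels = "matrix", originSide = "integer",
                 method = "character")
)

setValidity("CanvasImage", function(object) {
  msg <- character()
  if (!all(dim(object@pixels) == c(210L, 210L))) {
    msg <- c(msg, "canvas must be exactly 210 x 210")
  }
  ok <- switch(object@method,
    identity = object@originSide == 210L,
    fourier_downsample = object@originSide > 210L,
    zero_pad = object@originSide < 210L,
    FALSE)
  if (!isTRUE(ok)) {
    msg <- c(msg, "method inconsistent with originSide")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CanvasImage", function(object) {
  cat(sprintf("CanvasImage: 210 x 210 (from %d px, %s)\n",
              object@originSide, object@method))
})

#' @rdname CanvasImage-class
#' @param object a \code{CanvasImage}.
#' @export
canvasPixels <- function(object) object@pixels

#' @rdname CanvasImage-class
#' @export
canvasMethod <- function(object) object@method

#' @rdname CanvasImage-class
#' @export
originSide <- function(object) object@originSide

#' MassCalibration: intensity-to-mass conversion factor
#'
#' A scalar factor converting summed background-subtracted pixel intensity
#' times pixel area (Angstrom^2) into kilodaltons, fitted on known-mass
#' standards as the least-squares slope through the origin of mass on
#' integrated intensity.
#'
#' @slot factorC kDa per (intensity * A^2), > 0.
#' @slot nPoints number of calibration pairs used in the fit.
#' @slot residualRms root-mean-square residual of the fit, in kDa.
#' @seealso [fitCalibration()], [estimateMass()]
#' @export
setClass("MassCalibration",
  representation(factorC = "numeric", nPoints = "integer",
                 residualRms = "numeric")
)

setValidity("MassCalibration", function(object) {
  msg <- character()
  if (length(object@factorC) != 1L || !is.finite(object@factorC) ||
      object@factorC <= 0) {
    msg <- c(msg, "'factorC' must be a single finite positive number")
  }
  if (object@nPoints < 1L) msg <- c(msg, "'nPoints' must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MassCalibration", function(object) {
  cat(sprintf(
    "MassCalibration: %.6g kDa per intensity*A^2 (%d points, rms %.3g kDa)\n",
    object@factorC, object@nPoints, object@residualRms))
})

#' @rdname MassCalibration-class
#' @param object a \code{MassCalibration}.
#' @export
calibrationFactor <- function(object) object@factorC

#' ScorerModel: the trained CNN quality regressor
#'
#' Maps a 210 x 210 canvas image plus six scaled metadata features to one
#' continuous quality score (lower is better; nominally 1 = best grade to
#' 5 = worst grade, but the regression output is deliberately unbounded so
#' classes worse than the worst training class score above 5).
#'
#' @slot params named list of weight arrays.
#' @slot arch list describing the layer sequence (structural record).
#' @slot config the [scorerConfig()] the model was built with.
#' @slot featureStats list with per-metadata-feature \code{mean} and
#'   \code{sd} from the training split (used to z-score features at
#'   inference time).
#' @slot history data.frame of per-epoch train/validation MSE.
#' @slot trained logical(1).
#' @export
setClass("ScorerModel",
  representation(params = "list", arch = "list", config = "list",
                 featureStats = "list", history = "data.frame",
                 trained = "logical")
)

setMethod("show", "ScorerModel", function(object) {
  w <- paste(object@config$channelWidths, collapse = "/")
  np <- sum(vapply(object@params$weights, length, numeric(1)))
  cat(sprintf(
    "ScorerModel: %s (%s), widths %s, %d parameters; %d training epochs\n",
    if (object@trained) "trained" else "untrained",
    "residual CNN + 6 metadata features", w, np, nrow(object@history)))
})

#' @rdname ScorerModel-class
#' @param object a \code{ScorerModel}.
#' @export
trainingHistory <- function(object) object@history

#' SiftResult: outcome of the iterative classify-score-route policy
#'
#' @slot batches named list of three nested integer vectors of particle ids
#'   (\code{le2.5}, \code{le3.5}, \code{le4.5}) from the final pooled
#'   classification.
#' @slot discarded integer vector of discarded particle ids.
#' @slot particles final particle table (data.frame).
#' @slot audit character vector of line-oriented JSON audit records, one
#'   per round.
#' @slot rounds number of classification rounds actually executed
#'   (including the final pooled one).
#' @export
setClass("SiftResult",
  representation(batches = "list", discarded = "integer",
                 particles = "data.frame", audit = "character",
                 rounds = "integer")
)

setMethod("show", "SiftResult", function(object) {
  cat(sprintf(
    "SiftResult: %d rounds; batches <=2.5: %d, <=3.5: %d, <=4.5: %d; discarded: %d\n",
    object@rounds, length(object@batches$le2.5), length(object@batches$le3.5),
    length(object@batches$le4.5), length(object@discarded)))
})

#' @rdname SiftResult-class
#' @param object a \code{SiftResult}.
#' @export
siftBatches <- function(object) object@batches

#' @rdname SiftResult-class
#' @export
siftDiscarded <- function(object) object@discarded

#' @rdname SiftResult-class
#' @export
siftAudit <- function(object) object@audit

`%||%` <- function(a, b) if (is.null(a)) b else a
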