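# Mapping arbitrary square class averages onto the fixed 210 x 210 canvas.
#
# Large images are down-sampled by Fourier cropping (keep the central
# 210 x 210 block of the centered 2D spectrum), which preserves native
# low-frequency features instead of interpolating. Small images are
# standardized and placed centered in a zero field, so the padding matches
# the background statistics of a standardized class average.

CANVAS_SIDE <- 210L
MIN_INPUT_SIDE <- 31L

.fftshift2 <- function(m) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1L - d[1] %/% 2L) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L - d[2] %/% 2L) %% d[2]) + 1L
  m[i, j, drop = FALSE]
}

.ifftshift2 <- function(m) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1L + d[1] %/% 2L) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L + d[2] %/% 2L) %% d[2]) + 1L
  m[i, j, drop = FALSE]
}

# conjugate mirror on the uncentered grid: C'[k] = Conj(C[(-k) mod n])
.conjFlip <- function(m) {
  d <- dim(m)
  i <- c(1L, rev(seq.int(2L, d[1])))
  j <- c(1L, rev(seq.int(2L, d[2])))
  Conj(m[i, j, drop = FALSE])
}

#' Fourier-crop a square image to a smaller side
#'
#' Down-samples by keeping only the central (lowest-frequency)
#' \code{outSide x outSide} block of the centered 2D spectrum and inverse
#' transforming, so native low-frequency features are carried over exactly.
#' The DC term is normalized such that the real-space mean of the output
#' equals the input mean. The unpaired Nyquist row/column of the cropped
#' band is Hermitian-symmetrized, so the inverse transform is real to
#' machine precision (the discarded imaginary residue is asserted to be
#' below 1e-6 relative).
#'
#' @param image square numeric matrix with side > \code{outSide}.
#' @param outSide target side in px (default: the 210 px model canvas).
#' @return \code{outSide x outSide} numeric matrix.
#' @examples
#' x <- outer(1:420, 1:420, function(i, j) cos(2 * pi * 3 * i / 420))
#' y <- fourierCrop(x, 210)
#' abs(mean(y) - mean(x)) < 1e-9
#' @export
fourierCrop <- function(image, outSide = CANVAS_SIDE) {
  s <- nrow(image)
  outSide <- as.integer(outSide)
  if (ncol(image) != s) stop("image must be square")
  if (s <= outSide) stop("fourierCrop requires input side > output side")
  F <- .fftshift2(stats::fft(image))
  c0 <- floor(s / 2) + 1L               # DC index after centering
  half <- floor(outSide / 2)
  keep <- seq.int(c0 - half, c0 + (outSide - half - 1L))
  C <- .ifftshift2(F[keep, keep, drop = FALSE])
  C <- (C + .conjFlip(C)) / 2           # enforce Hermitian symmetry
  z <- stats::fft(C, inverse = TRUE) / s^2
  re <- Re(z)
  scale <- max(abs(re), .Machine$double.eps)
  if (max(abs(Im(z))) / scale > 1e-6) {
    stop("Fourier crop produced a non-negligible imaginary residue")
  }
  re
}

# zero mean / unit SD; constant images become all zeros
.standardize <- function(image) {
  m <- mean(image)
  s <- stats::sd(as.vector(image))
  if (!is.finite(s) || s == 0) {
    image - m
  } else {
    (image - m) / s
  }
}

#' Map a square class-average image onto the 210 x 210 model canvas
#'
#' Any square image with side >= 31 px is mapped onto the fixed canvas the
#' CNN consumes: sides above 210 are Fourier down-sampled
#' (see [fourierCrop()]); sides below 210 are standardized to zero mean and
#' unit SD and placed centered in a 210 x 210 zero field (an odd size
#' remainder pads one extra row/column at the bottom/right); a 210 px image
#' is returned as a standardized copy. Down-sampled images are standardized
#' after cropping, so every canvas carries comparable statistics.
#'
#' @param image square numeric matrix, side in \code{[31, ...]}, all values
#'   finite.
#' @return A [CanvasImage-class].
#' @examples
#' cv <- resampleToCanvas(matrix(rnorm(64^2), 64, 64))
#' canvasMethod(cv)
#' @export
resampleToCanvas <- function(image) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop("input must be a square matrix")
  }
  s <- nrow(image)
  if (s < MIN_INPUT_SIDE) {
    stop(sprintf("input side %d px is below minimum input size %d x %d",
                 s, MIN_INPUT_SIDE, MIN_INPUT_SIDE))
  }
  if (!all(is.finite(image))) stop("image contains NaN or infinite pixels")
  if (s > CANVAS_SIDE) {
    px <- .standardize(fourierCrop(image, CANVAS_SIDE))
    method <- "fourier_downsample"
  } else if (s < CANVAS_SIDE) {
    px <- matrix(0, CANVAS_SIDE, CANVAS_SIDE)
    off <- floor((CANVAS_SIDE - s) / 2)           # extra pad goes bottom/right
    px[off + seq_len(s), off + seq_len(s)] <- .standardize(image)
    method <- "zero_pad"
  } else {
    px <- .standardize(image)
    method <- "identity"
  }
  new("CanvasImage", pixels = px, originSide = as.integer(s),
      method = method)
}
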