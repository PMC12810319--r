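# Pixel-intensity mass estimation for 2D class averages.
#
# Signal pixels are defined as those lying more than three standard
# deviations above the image mean (statistics over the whole image, no
# morphology). The particle mass follows from the background-subtracted
# intensity sum scaled by the pixel area and a calibration factor fitted on
# known-mass standards.

#' Segment the particle signal of a class average
#'
#' Returns the binary particle mask: \code{TRUE} exactly where the pixel
#' value exceeds \code{mean(image) + 3 * sd(image)}, with both statistics
#' taken over all pixels. No morphological clean-up is applied; an empty
#' mask is a legal result (e.g. for a constant image).
#'
#' @param image finite numeric matrix.
#' @return logical matrix of the same dimension.
#' @export
segmentParticle <- function(image) {
  if (!all(is.finite(image))) stop("image must be finite")
  thr <- mean(image) + 3 * stats::sd(as.vector(image))
  if (!is.finite(thr)) thr <- Inf   # sd undefined for length-1 edge case
  image > thr
}

#' Estimate the particle mass of a class average
#'
#' Mass in kDa is the calibration factor times the sum, over the segmented
#' particle pixels, of the intensity above the background mean, times the
#' pixel area in Angstrom^2:
#' \deqn{M = c \cdot \sum_{p \in mask} (I_p - \bar{I}_{bg}) \cdot a^2}
#' where \eqn{a} is the pixel size. An empty mask yields mass 0.
#'
#' @param image finite numeric matrix.
#' @param pixelSize pixel size in A/px (> 0).
#' @param cal a [MassCalibration-class]; defaults to the unit calibration
#'   (factor 1), useful for reporting raw integrated intensities.
#' @return estimated mass in kDa (>= 0 for real particles; the background
#'   subtraction makes the value offset-invariant).
#' @examples
#' img <- matrix(0, 64, 64); img[30:39, 30:39] <- 2
#' estimateMass(img, pixelSize = 1, cal = unitCalibration())
#' @export
estimateMass <- function(image, pixelSize, cal = unitCalibration()) {
  if (length(pixelSize) != 1L || !is.finite(pixelSize) || pixelSize <= 0) {
    stop("pixelSize must be a single positive number (A/px)")
  }
  mask <- segmentParticle(image)
  if (!any(mask)) return(0)
  bg <- mean(image[!mask])
  if (!is.finite(bg)) bg <- 0       # mask covers everything
  cal@factorC * sum(image[mask] - bg) * pixelSize^2
}

#' Summed background-subtracted intensity of a class average
#'
#' The quantity calibrated against known masses: equivalent to
#' [estimateMass()] under the unit calibration.
#'
#' @inheritParams estimateMass
#' @return intensity * A^2.
#' @export
integratedIntensity <- function(image, pixelSize) {
  estimateMass(image, pixelSize, unitCalibration())
}

#' @rdname MassCalibration-class
#' @export
unitCalibration <- function() {
  new("MassCalibration", factorC = 1, nPoints = 1L, residualRms = 0)
}

#' Fit the intensity-to-mass calibration on known-mass standards
#'
#' Plotting integrated background-subtracted intensities against known
#' masses gives a line through the origin; the calibration factor is the
#' least-squares slope constrained through the origin,
#' \deqn{c = \sum_i I_i M_i / \sum_i I_i^2.}
#'
#' @param intensity integrated intensities (intensity * A^2), > 0 overall.
#' @param mass known masses in kDa, same length.
#' @return A [MassCalibration-class].
#' @examples
#' fitCalibration(c(100, 200), c(50, 100))   # factor 0.5
#' @export
fitCalibration <- function(intensity, mass) {
  if (length(intensity) < 1L || length(intensity) != length(mass)) {
    stop("need >= 1 (intensity, mass) pair of equal length")
  }
  if (all(intensity == 0)) stop("all-zero intensities: cannot calibrate")
  factorC <- sum(intensity * mass) / sum(intensity^2)
  if (!is.finite(factorC) || factorC <= 0) {
    stop("calibration slope must be positive and finite")
  }
  res <- mass - factorC * intensity
  new("MassCalibration", factorC = factorC,
      nPoints = length(intensity),
      residualRms = sqrt(mean(res^2)))
}

#' Read a 2-column calibration table and fit the calibration
#'
#' @param path CSV with columns \code{summed_intensity} and \code{mass_kda}.
#' @return A [MassCalibration-class].
#' @export
fitCalibrationFile <- function(path) {
  df <- read.csv(path)
  need <- c("summed_intensity", "mass_kda")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fitCalibration(df$summed_intensity, df$mass_kda)
}

#' Persist / restore a calibration as a key-value text file
#'
#' @param cal a [MassCalibration-class].
#' @param path text file path.
#' @return \code{path} (write) or the restored calibration (read).
#' @export
writeCalibration <- function(cal, path) {
  writeLines(c(
    sprintf("factor_c\t%.15g", cal@factorC),
    sprintf("n_points\t%d", cal@nPoints),
    sprintf("residual_rms\t%.15g", cal@residualRms)
  ), path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  kv <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("key", "value"))
  get1 <- function(k) as.numeric(kv$value[kv$key == k][1])
  new("MassCalibration", factorC = get1("factor_c"),
      nPoints = as.integer(get1("n_points")),
      residualRms = get1("residual_rms"))
}

#' Histogram mode of a set of masses
#'
#' Mode of a continuous sample via a histogram with Freedman-Diaconis bin
#' width (2 * IQR / n^(1/3)); if the IQR is zero the whole range collapses
#' into a single bin. Bins run right-open from the minimum; the mode is the
#' centre of the most-populated bin, ties resolved to the lowest bin.
#'
#' @param masses numeric vector (kDa).
#' @return mode estimate in kDa.
#' @export
massMode <- function(masses) {
  n <- length(masses)
  if (!n) stop("empty mass list")
  lo <- min(masses); hi <- max(masses)
  iqr <- stats::quantile(masses, 0.75, names = FALSE) -
         stats::quantile(masses, 0.25, names = FALSE)
  h <- 2 * iqr / n^(1 / 3)
  if (!is.finite(h) || h <= 0 || hi == lo) {
    return((lo + hi) / 2)
  }
  nbin <- max(1L, ceiling((hi - lo) / h))
  edges <- lo + h * seq.int(0L, nbin)
  # right-open bins [edge_k, edge_{k+1}); top value falls in the last bin
  idx <- pmin(findInterval(masses, edges), nbin)
  counts <- tabulate(idx, nbins = nbin)
  k <- which.max(counts)            # ties -> lowest bin
  lo + h * (k - 0.5)
}

#' Mass-deviation features across a stack of class averages
#'
#' For each class, the signed deviation (kDa) of its estimated mass from
#' the stack's mean, median and histogram mode mass. These are three of the
#' six metadata features the CNN consumes alongside the image.
#'
#' @param masses per-class estimated masses in kDa (>= 0), length >= 1.
#' @return data.frame with columns \code{estMass}, \code{devMeanMass},
#'   \code{devMedianMass}, \code{devModeMass}.
#' @examples
#' massDeviationFeatures(c(90, 100, 110))$devMeanMass   # -10  0  10
#' @export
massDeviationFeatures <- function(masses) {
  if (!length(masses)) stop("empty mass list")
  if (any(!is.finite(masses)) || any(masses < 0)) {
    stop("masses must be finite and >= 0")
  }
  data.frame(
    estMass = masses,
    devMeanMass = masses - mean(masses),
    devMedianMass = masses - stats::median(masses),
    devModeMass = masses - massMode(masses)
  )
}

#' Attach mass features to a class record table
#'
#' Estimates each class's mass from its image and fills the \code{estMass}
#' and deviation columns of the record table.
#'
#' @param stack a [ClassAverageStack-class].
#' @param records class record data.frame, one row per image (matched by
#'   \code{classIndex} order).
#' @param cal a [MassCalibration-class].
#' @return the records with mass columns filled.
#' @export
addMassFeatures <- function(stack, records, cal = unitCalibration()) {
  stopifnot(is(stack, "ClassAverageStack"))
  if (nrow(records) != nClasses(stack)) {
    stop("one record per class image required")
  }
  masses <- vapply(seq_len(nClasses(stack)), function(i) {
    estimateMass(classImage(stack, i), pixelSize(stack), cal)
  }, numeric(1))
  masses <- pmax(masses, 0)
  feats <- massDeviationFeatures(masses)
  records$estMass <- feats$estMass
  records$devMeanMass <- feats$devMeanMass
  records$devMedianMass <- feats$devMedianMass
  records$devModeMass <- feats$devModeMass
  records
}
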