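# Synthetic graded class averages.
#
# Emulates what distinguishes good from bad 2D class averages for the
# purposes of this package: a projection-like shape whose integrated
# background-subtracted intensity encodes a target mass, degraded by a
# grade-scheduled Gaussian blur, correlated additive noise and occasional
# artifacts (streaks, edge clipping), with metadata (FRC-proxy resolution,
# class distribution, pixel size) that co-varies with grade the way real
# classification metadata does. Grade 5 images are noise/artifact
# dominated. It makes no claim to physical image formation (no CTF, dose
# or ice effects).

SYNTH_SHAPES <- c("disc", "annulus", "two_lobe", "noise_only")

# degradation schedules over the grade axis g in [1, 5]; blur and noise are
# geometric (quality degrades multiplicatively), artifacts linear
.blurSigmaPx <- function(g) 0.2 * 30^((g - 1) / 4)
.noiseSdRel <- function(g) 0.02 * 50^((g - 1) / 4)
.artifactProb <- function(g) 0.225 * (g - 1)

# FRC-proxy: frequency where the blur transfer function exp(-2 pi^2 s^2 f^2)
# falls to 0.5, capped at Nyquist, mapped to Angstrom
.frcProxy <- function(blurSigma, pixelSizeA) {
  f05 <- sqrt(log(2) / (2 * pi^2 * blurSigma^2))
  pixelSizeA / min(f05, 0.5)
}

# Gaussian blur in Fourier space (periodic boundaries; preserves the sum)
.gaussianBlurFT <- function(image, sigma) {
  if (sigma <= 0) return(image)
  n <- nrow(image)
  f <- (seq_len(n) - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  tf <- exp(-2 * pi^2 * sigma^2 * f^2)
  T2 <- outer(tf, tf)
  Re(stats::fft(stats::fft(image) * T2, inverse = TRUE)) / n^2
}

.renderShape <- function(shape, side, diameterPx, center = c(0, 0),
                         angle = 0) {
  R <- diameterPx / 2
  cx <- (side + 1) / 2 + center[1]
  cy <- (side + 1) / 2 + center[2]
  xs <- matrix(seq_len(side), side, side) - cx
  ys <- matrix(seq_len(side), side, side, byrow = TRUE) - cy
  switch(shape,
    disc = (xs^2 + ys^2 <= R^2) * 1,
    annulus = {
      r2 <- xs^2 + ys^2
      (r2 <= R^2 & r2 > (0.55 * R)^2) * 1
    },
    two_lobe = {
      r <- 0.62 * R
      dx <- 0.5 * R * cos(angle); dy <- 0.5 * R * sin(angle)
      (((xs - dx)^2 + (ys - dy)^2 <= r^2) |
         ((xs + dx)^2 + (ys + dy)^2 <= r^2)) * 1
    },
    noise_only = matrix(0, side, side),
    stop("unknown particle shape '", shape, "'"))
}

#' Specification of one synthetic class average
#'
#' @param trueGrade real quality grade in [1, 5] (1 = best).
#' @param shape one of \code{disc}, \code{annulus}, \code{two_lobe},
#'   \code{noise_only}.
#' @param diameterPx particle diameter in px.
#' @param side image side in px.
#' @param pixelSizeA pixel size in A/px.
#' @param targetMassKda target particle mass under the unit calibration.
#' @param seed integer seed; identical (spec, seed) gives a bit-identical
#'   image.
#' @return a validated list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(trueGrade, shape = "disc", diameterPx = 32L,
                          side = 128L, pixelSizeA = 1.0,
                          targetMassKda = 400, seed = 1L) {
  if (!is.numeric(trueGrade) || trueGrade < 1 || trueGrade > 5) {
    stop("trueGrade must lie in [1, 5]")
  }
  if (!shape %in% SYNTH_SHAPES) {
    stop("shape must be one of ", paste(SYNTH_SHAPES, collapse = ", "))
  }
  structure(list(trueGrade = trueGrade, shape = shape,
                 diameterPx = as.integer(diameterPx),
                 side = as.integer(side), pixelSizeA = pixelSizeA,
                 targetMassKda = targetMassKda, seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Render one synthetic class average with its metadata record
#'
#' The shape is rendered, blurred with the grade-scheduled Gaussian, and
#' normalized so the integrated intensity times pixel area equals the
#' target mass under the unit calibration (the blur is sum-preserving, so
#' the normalization survives it). Correlated Gaussian noise scaled by the
#' grade schedule is added, plus, with grade-scheduled probability, an
#' artifact: a smooth streak or clipping of the particle at the image
#' edge. The accompanying record carries the FRC-proxy resolution (blur
#' transfer function at half-height, with a small lognormal jitter), the
#' pixel size, and the true grade.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{image} (side x side matrix), \code{grade}
#'   (numeric), and \code{record} (one-row class record data.frame).
#' @export
makeClassAverage <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  g <- spec$trueGrade
  withSeed(spec$seed, {
    side <- spec$side
    blurSigma <- .blurSigmaPx(g)
    clipEdge <- FALSE
    streak <- FALSE
    if (runif(1) < .artifactProb(g)) {
      if (runif(1) < 0.5) clipEdge <- TRUE else streak <- TRUE
    }
    center <- c(0, 0)
    if (clipEdge && spec$shape != "noise_only") {
      # push the particle against a random edge so it clips
      ang <- runif(1, 0, 2 * pi)
      d <- side / 2 - spec$diameterPx / 5
      center <- d * c(cos(ang), sin(ang))
    }
    base <- .renderShape(spec$shape, side, spec$diameterPx, center,
                         angle = runif(1, 0, pi))
    img <- .gaussianBlurFT(base, blurSigma)
    tot <- sum(img) * spec$pixelSizeA^2
    if (tot > 0) {
      img <- img * spec$targetMassKda / tot
      amp <- spec$targetMassKda /
        (pi * (spec$diameterPx / 2)^2 * spec$pixelSizeA^2)
    } else {
      img <- matrix(0, side, side)
      amp <- spec$targetMassKda /
        (pi * (spec$diameterPx / 2)^2 * spec$pixelSizeA^2)
    }
    if (streak) {
      ang <- runif(1, 0, pi)
      off <- runif(1, -side / 4, side / 4)
      xs <- matrix(seq_len(side), side, side) - (side + 1) / 2
      ys <- matrix(seq_len(side), side, side, byrow = TRUE) - (side + 1) / 2
      dist <- abs(xs * sin(ang) - ys * cos(ang) + off)
      img <- img + 1.2 * amp * exp(-dist^2 / (2 * 2.5^2))
    }
    noise <- matrix(rnorm(side^2), side, side)
    noise <- .gaussianBlurFT(noise, 3)
    noise <- noise / stats::sd(as.vector(noise))
    img <- img + .noiseSdRel(g) * amp * noise
    frc <- .frcProxy(blurSigma, spec$pixelSizeA) * exp(rnorm(1, 0, 0.05))
    frc <- max(frc, 2 * spec$pixelSizeA)
    grade <- c("A", "B", "C", "D", "F")[min(5L, max(1L, round(g)))]
    record <- classRecords(0L, spec$pixelSizeA, frc, 1,
                           grade = grade,
                           score = gradeToScore(grade))
    list(image = img, grade = g, record = record)
  })
}

#' Generate a labeled synthetic training corpus
#'
#' Draws \code{n} class averages with integer grades from the given
#' mixture, heterogeneous shapes, diameters, pixel sizes and masses;
#' computes cohort-level mass-deviation features from the unit-calibration
#' mass estimates of the generated images; and assembles labels as the
#' numeric scores of the true grades. Class distributions are drawn so
#' better classes tend to hold more particles, then normalized over the
#' cohort.
#'
#' @param n corpus size (>= 1).
#' @param gradeMixture probabilities over grades 1..5, summing to 1.
#' @param seed integer seed.
#' @param side image side in px.
#' @return list with \code{images} (list of matrices), \code{meta}
#'   (n x 6 matrix in the order pixelSize, frcResolution,
#'   classDistribution, devMeanMass, devMedianMass, devModeMass),
#'   \code{labels} (numeric scores), \code{grades} (integer), and
#'   \code{records} (class record data.frame).
#' @export
makeLabeledCorpus <- function(n, gradeMixture = rep(0.2, 5), seed = 7L,
                              side = 128L) {
  if (n < 1L) stop("n must be >= 1")
  if (length(gradeMixture) != 5L || any(gradeMixture < 0)) {
    stop("gradeMixture must be 5 non-negative probabilities")
  }
  if (abs(sum(gradeMixture) - 1) > 1e-6) {
    stop("gradeMixture must sum to 1")
  }
  withSeed(seed, {
    grades <- sample.int(5L, n, replace = TRUE, prob = gradeMixture)
    shapes <- vapply(grades, function(g) {
      if (g == 5L) {
        sample(c("noise_only", "disc"), 1L, prob = c(0.8, 0.2))
      } else {
        sample(c("disc", "annulus", "two_lobe"), 1L)
      }
    }, character(1))
    diam <- sample(24:48, n, replace = TRUE)
    px <- sample(c(0.8, 1.0, 1.2), n, replace = TRUE)
    mass <- 0.012 * (diam * px)^3          # kDa, grows with particle volume
    itemSeeds <- sample.int(2^30, n)
    images <- vector("list", n)
    frc <- numeric(n)
    gradeChr <- character(n)
    for (i in seq_len(n)) {
      r <- makeClassAverage(syntheticSpec(
        trueGrade = grades[i], shape = shapes[i], diameterPx = diam[i],
        side = side, pixelSizeA = px[i], targetMassKda = mass[i],
        seed = itemSeeds[i]))
      images[[i]] <- r$image
      frc[i] <- r$record$frcResolution
      gradeChr[i] <- r$record$grade
    }
    estMass <- vapply(seq_len(n), function(i) {
      max(0, integratedIntensity(images[[i]], px[i]))
    }, numeric(1))
    feats <- massDeviationFeatures(estMass)
    # class distributions are normalized within pseudo classification runs
    # of 8-25 classes, so the values match the per-class fractions a real
    # run (or the synthetic backend) produces, not 1/n of a huge corpus
    runId <- integer(n)
    i <- 1L; r <- 1L
    while (i <= n) {
      k <- min(n - i + 1L, sample(8:25, 1L))
      runId[i:(i + k - 1L)] <- r
      i <- i + k; r <- r + 1L
    }
    w <- stats::rgamma(n, shape = 6 - grades)
    dist <- stats::ave(w, runId, FUN = function(v) v / sum(v))
    meta <- cbind(pixelSize = px, frcResolution = frc,
                  classDistribution = dist,
                  devMeanMass = feats$devMeanMass,
                  devMedianMass = feats$devMedianMass,
                  devModeMass = feats$devModeMass)
    records <- classRecords(seq_len(n) - 1L, px, frc, dist,
                            grade = gradeChr, score = NA_real_,
                            checkSum = FALSE)
    records$runId <- runId
    records$estMass <- feats$estMass
    records$devMeanMass <- feats$devMeanMass
    records$devMedianMass <- feats$devMedianMass
    records$devModeMass <- feats$devModeMass
    list(images = images, meta = meta,
         labels = gradeToScore(gradeChr), grades = grades,
         records = records)
  })
}

#' Integrated spectral power above a radial frequency
#'
#' Diagnostic used to verify that the generator's degradation schedules
#' order grades spectrally: total 2D power at radial frequencies above
#' \code{fmin} (cycles/px), DC excluded.
#'
#' @param image numeric matrix.
#' @param fmin radial frequency cutoff in cycles/px.
#' @return scalar power.
#' @export
highFrequencyPower <- function(image, fmin = 0.25) {
  n <- nrow(image)
  f <- (seq_len(n) - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  r2 <- outer(f^2, f^2, "+")
  P <- Mod(stats::fft(image))^2
  sum(P[r2 > fmin^2]) / n^2
}

#' A synthetic 2D-classification backend
#'
#' Fulfils the pluggable classification contract of the sift policy with
#' no external software: particles carrying latent true grades are grouped
#' by a noise-perturbed grade into k classes (emulating that 2D
#' classification co-locates particles of similar quality), and each class
#' is rendered as a synthetic class average at the median member grade,
#' with metadata (class distribution = member fraction, FRC proxy, mass
#' features) computed from the rendered stack.
#'
#' @param cohort data.frame with one row per particle: \code{particleId},
#'   \code{trueGrade} (in [1, 5]) and optionally \code{diameterPx},
#'   \code{pixelSize}, \code{massKda}.
#' @param kClasses default number of classes per run.
#' @param seed default seed.
#' @param boxSidePx side of the rendered class averages in px.
#' @return a backend object: list with a \code{classify(particleIds,
#'   params)} function returning \code{assignment} (1-based class index
#'   per particle), \code{stack} (a [ClassAverageStack-class]) and
#'   \code{records} (class record data.frame with mass features filled).
#' @export
syntheticBackend <- function(cohort, kClasses = 10L, seed = 1L,
                             boxSidePx = 128L) {
  stopifnot(is.data.frame(cohort),
            all(c("particleId", "trueGrade") %in% names(cohort)))
  if (is.null(cohort$diameterPx)) cohort$diameterPx <- 32L
  if (is.null(cohort$pixelSize)) cohort$pixelSize <- 1.0
  if (is.null(cohort$massKda)) {
    cohort$massKda <- 0.012 * (cohort$diameterPx * cohort$pixelSize)^3
  }
  lut <- cohort
  rownames(lut) <- as.character(lut$particleId)
  list(
    kClasses = as.integer(kClasses),
    classify = function(particleIds, params = list()) {
      k <- as.integer(params$kClasses %||% kClasses)
      n <- length(particleIds)
      if (k > n) {
        stop(sprintf("kClasses (%d) exceeds number of particles (%d)", k, n))
      }
      runSeed <- as.integer(params$seed %||% seed)
      rows <- lut[as.character(particleIds), ]
      withSeed(runSeed, {
        noisy <- rows$trueGrade + rnorm(n, 0, 0.25)
        assignment <- as.integer(
          cut(rank(noisy, ties.method = "first"), breaks = k))
        classSeeds <- sample.int(2^30, k)
        imgs <- vector("list", k)
        frc <- numeric(k)
        counts <- tabulate(assignment, nbins = k)
        medGrade <- numeric(k)
        for (c in seq_len(k)) {
          members <- which(assignment == c)
          medGrade[c] <- min(5, max(1, stats::median(rows$trueGrade[members])))
          shape <- if (medGrade[c] >= 4.5) "noise_only" else "disc"
          r <- makeClassAverage(syntheticSpec(
            trueGrade = medGrade[c], shape = shape,
            diameterPx = as.integer(stats::median(rows$diameterPx[members])),
            side = as.integer(boxSidePx),
            pixelSizeA = rows$pixelSize[1],
            targetMassKda = stats::median(rows$massKda[members]),
            seed = classSeeds[c]))
          imgs[[c]] <- r$image
          frc[c] <- r$record$frcResolution
        }
        stack <- classAverageStack(imgs, pixelSize = rows$pixelSize[1],
                                   sourceId = sprintf("synthetic_run_seed%d",
                                                      runSeed))
        records <- classRecords(seq_len(k) - 1L, rows$pixelSize[1], frc,
                                counts / n)
        records$trueGrade <- medGrade
        records <- addMassFeatures(stack, records)
        list(assignment = assignment, stack = stack, records = records)
      })
    })
}
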