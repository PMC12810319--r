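# The iterative classify -> score -> route engine.
#
# Particles whose class scores at most the accept cutoff are mostly banked
# (set aside, rejoining only the final pooled classification), particles
# at or above the discard cutoff are dropped permanently, and mid-range
# particles keep iterating. The number of rounds follows the extraction
# box side as a proxy for particle size. After the last round, banked and
# surviving particles are pooled, classified and scored once more, and
# split into three nested batches at the final score thresholds.

#' Policy configuration for the iterative sift
#'
#' @param acceptCutoff score at/below which a particle counts as good
#'   (default 2.5).
#' @param discardCutoff score at/above which a particle is discarded
#'   (default 4.5).
#' @param bankFraction fraction of good particles banked (removed from
#'   further iterations) each round (default 0.70; the remaining 30%
#'   continue iterating).
#' @param finalThresholds strictly increasing score thresholds of the
#'   three nested final batches (default 2.5, 3.5, 4.5).
#' @param seed integer seed; per-round sampling seeds are derived from it.
#' @return a validated list of class \code{"policyConfig"}.
#' @export
policyConfig <- function(acceptCutoff = 2.5, discardCutoff = 4.5,
                         bankFraction = 0.70,
                         finalThresholds = c(2.5, 3.5, 4.5), seed = 1L) {
  cfg <- list(acceptCutoff = acceptCutoff, discardCutoff = discardCutoff,
              bankFraction = bankFraction,
              finalThresholds = finalThresholds, seed = as.integer(seed))
  if (!(cfg$acceptCutoff < cfg$discardCutoff)) {
    stop("acceptCutoff must be below discardCutoff")
  }
  if (!(cfg$bankFraction > 0 && cfg$bankFraction < 1)) {
    stop("bankFraction must lie in (0, 1)")
  }
  if (is.unsorted(cfg$finalThresholds, strictly = TRUE)) {
    stop("finalThresholds must be strictly increasing")
  }
  class(cfg) <- "policyConfig"
  cfg
}

#' Create a fresh particle table
#'
#' @param particleIds unique particle identifiers.
#' @return data.frame with columns \code{particleId}, \code{class},
#'   \code{score} and \code{state} (all particles start \code{working}).
#' @export
newParticleTable <- function(particleIds) {
  if (anyDuplicated(particleIds)) stop("particle ids must be unique")
  n <- length(particleIds)
  data.frame(particleId = particleIds,
             class = rep_len(NA_integer_, n),
             score = rep_len(NA_real_, n),
             state = rep_len("working", n),
             stringsAsFactors = FALSE)
}

#' Number of classify-score-route iterations for a box size
#'
#' Extraction box side in px acts as an indirect measure of particle
#' size: boxes under 200 px run 5 rounds, boxes of 200-300 px (inclusive)
#' run 3, larger boxes run 2.
#'
#' @param boxSidePx extraction box side in px (>= 1).
#' @return integer iteration count (5, 3 or 2).
#' @examples
#' iterationCount(150); iterationCount(250); iterationCount(350)
#' @export
iterationCount <- function(boxSidePx) {
  if (!is.finite(boxSidePx) || boxSidePx < 1) {
    stop("box side must be a positive number of pixels")
  }
  if (boxSidePx < 200) 5L else if (boxSidePx <= 300) 3L else 2L
}

#' Recommended 2D classification parameters for a box size
#'
#' Box sides below 200 px are treated as small particles: 3 A maximum
#' resolution, initial class uncertainty factor 3, force-max over
#' poses/shifts off, 40 online-EM iterations, batch size 400. Sides in
#' [200, 300] use the platform defaults. Larger boxes are classified in a
#' 100 px Fourier-cropped box (adaptive binning).
#'
#' @param boxSidePx extraction box side in px (>= 1).
#' @return named list describing the parameter tier.
#' @export
recommendClass2DParams <- function(boxSidePx) {
  if (!is.finite(boxSidePx) || boxSidePx < 1) {
    stop("box side must be a positive number of pixels")
  }
  if (boxSidePx < 200) {
    list(tier = "small", maxResA = 3, initialUncertainty = 3,
         forceMaxPosesShifts = FALSE, onlineEMIterations = 40L,
         batchSize = 400L)
  } else if (boxSidePx <= 300) {
    list(tier = "default")
  } else {
    list(tier = "large", cropToPx = 100L)
  }
}

#' One routing step of the sift policy
#'
#' Every working particle must carry a current class score. Particles
#' scoring at or above the discard cutoff are discarded; of those scoring
#' at or below the accept cutoff, a seeded uniform-random bank fraction
#' (70% by default) is banked, the rest keep working; mid-range particles
#' keep working. Banked and discarded states are permanent.
#'
#' @param particles particle table (see [newParticleTable()]).
#' @param config a [policyConfig()].
#' @param roundIndex 1-based round number (drives the derived sampling
#'   seed).
#' @return the updated particle table.
#' @export
routeParticles <- function(particles, config = policyConfig(),
                           roundIndex = 1L) {
  w <- which(particles$state == "working")
  if (!length(w)) return(particles)
  if (anyNA(particles$score[w])) {
    stop("unscored working particle(s): ",
         paste(utils::head(particles$particleId[w][is.na(particles$score[w])], 3L),
               collapse = ", "))
  }
  sc <- particles$score[w]
  particles$state[w[sc >= config$discardCutoff]] <- "discarded"
  good <- w[sc <= config$acceptCutoff]
  if (length(good)) {
    nBank <- round(config$bankFraction * length(good))
    bankIdx <- withSeed(config$seed + 7919L * as.integer(roundIndex), {
      if (nBank > 0L) sample(good, nBank) else integer()
    })
    particles$state[bankIdx] <- "banked"
  }
  particles
}

#' Split a scored pool into the three nested final batches
#'
#' Cumulative membership by score at or below each threshold; batches are
#' nested by construction.
#'
#' @param particleIds pooled particle ids.
#' @param scores final scores, parallel to \code{particleIds}.
#' @param thresholds increasing score thresholds (default 2.5, 3.5, 4.5).
#' @return named list of integer vectors, one per threshold
#'   (\code{le2.5} etc.).
#' @examples
#' finalBatches(1:4, c(2.0, 3.0, 4.0, 4.6))
#' @export
finalBatches <- function(particleIds, scores,
                         thresholds = c(2.5, 3.5, 4.5)) {
  if (length(particleIds) != length(scores)) {
    stop("ids and scores must be parallel")
  }
  if (length(particleIds) && anyNA(scores)) {
    stop("every pooled particle must be scored")
  }
  out <- lapply(thresholds, function(t) particleIds[scores <= t])
  names(out) <- sprintf("le%g", thresholds)
  out
}

.scoreStack <- function(model, stack, records) {
  if (is.function(model)) model(stack, records) else {
    scoreClasses(model, stack, records)
  }
}

.auditLine <- function(...) {
  as.character(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = 6L))
}

#' Run the full iterative sift
#'
#' Executes \code{iterationCount(boxSidePx)} rounds of classify ->
#' score -> route against the given classification backend, then pools
#' banked and surviving working particles, runs one final classification
#' and scoring, and splits the pool into the three nested batches at the
#' final thresholds. If the working set empties early, the remaining
#' rounds are skipped and logged. Identical inputs and seed give a
#' byte-identical audit log.
#'
#' @param particles particle table from [newParticleTable()].
#' @param backend classification backend (see [syntheticBackend()]): must
#'   provide \code{classify(particleIds, params)}.
#' @param model a trained [ScorerModel-class], or a function
#'   \code{(stack, records) -> scores} (e.g. an oracle scorer in tests).
#' @param boxSidePx extraction box side in px.
#' @param config a [policyConfig()].
#' @param kClasses number of 2D classes requested per round (capped at
#'   the number of particles in the round).
#' @return a [SiftResult-class].
#' @export
runSift <- function(particles, backend, model, boxSidePx,
                    config = policyConfig(), kClasses = 10L) {
  if (!nrow(particles)) stop("no particles to sift")
  nInput <- nrow(particles)
  nRounds <- iterationCount(boxSidePx)
  class2d <- recommendClass2DParams(boxSidePx)
  audit <- character()
  executed <- 0L
  for (r in seq_len(nRounds)) {
    wIds <- particles$particleId[particles$state == "working"]
    if (!length(wIds)) {
      audit <- c(audit, .auditLine(round = r, phase = "skipped",
                                   reason = "working set empty"))
      next
    }
    res <- tryCatch(
      backend$classify(wIds, params = list(
        kClasses = min(kClasses, length(wIds)),
        seed = config$seed + 104729L * r,
        class2d = class2d)),
      error = function(e) {
        stop(sprintf("classification backend failed in round %d: %s",
                     r, conditionMessage(e)), call. = FALSE)
      })
    scores <- .scoreStack(model, res$stack, res$records)
    m <- match(wIds, particles$particleId)
    particles$class[m] <- res$assignment
    particles$score[m] <- scores[res$assignment]
    particles <- routeParticles(particles, config, roundIndex = r)
    executed <- executed + 1L
    audit <- c(audit, .auditLine(
      round = r, phase = "iterate",
      nWorking = sum(particles$state == "working"),
      nBanked = sum(particles$state == "banked"),
      nDiscarded = sum(particles$state == "discarded"),
      classScores = round(scores, 6)))
  }
  poolIds <- particles$particleId[particles$state %in% c("working", "banked")]
  if (length(poolIds)) {
    res <- tryCatch(
      backend$classify(poolIds, params = list(
        kClasses = min(kClasses, length(poolIds)),
        seed = config$seed + 104729L * (nRounds + 1L),
        class2d = class2d)),
      error = function(e) {
        stop("classification backend failed in the final round: ",
             conditionMessage(e), call. = FALSE)
      })
    finalScores <- .scoreStack(model, res$stack, res$records)
    m <- match(poolIds, particles$particleId)
    particles$class[m] <- res$assignment
    particles$score[m] <- finalScores[res$assignment]
    executed <- executed + 1L
    batches <- finalBatches(poolIds, particles$score[m],
                            config$finalThresholds)
    audit <- c(audit, .auditLine(
      round = nRounds + 1L, phase = "final", nPooled = length(poolIds),
      classScores = round(finalScores, 6),
      batchSizes = lengths(batches)))
  } else {
    batches <- finalBatches(integer(), numeric(), config$finalThresholds)
    audit <- c(audit, .auditLine(round = nRounds + 1L, phase = "final",
                                 nPooled = 0L))
  }
  discarded <- particles$particleId[particles$state == "discarded"]
  stopifnot(length(poolIds) + length(discarded) == nInput)
  new("SiftResult",
      batches = lapply(batches, as.integer),
      discarded = as.integer(discarded),
      particles = particles, audit = audit, rounds = executed)
}
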