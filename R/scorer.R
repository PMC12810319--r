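# The CNN quality regressor: grade mapping, architecture construction,
# seeded training with Adam/MSE, inference and evaluation.
#
# Architecture constraints honored throughout: residual blocks with batch
# normalization after every convolution; downsampling only via pairs of
# consecutive 2x2 stride-2 convolutions (no pooling layers in the trunk);
# adaptive average pooling to a fixed 6x6 map; the six scaled metadata
# features concatenated after pooling; a single linear output trained with
# MSE (no softmax), so scores are unbounded.

GRADE_LEVELS <- c(A = 1, B = 2, C = 3, D = 4, F = 5)
META_FEATURES <- c("pixelSize", "frcResolution", "classDistribution",
                   "devMeanMass", "devMedianMass", "devModeMass")

#' Map an expert grade to its numeric quality score
#'
#' The A-F expert rubric (A: best, secondary structure, very sharp; F:
#' unusable, nothing resembling a particle) maps linearly onto the score
#' anchors 1.0 (best) to 5.0 (worst).
#'
#' @param grade character vector with elements in \code{A, B, C, D, F}.
#' @return numeric scores in \code{1, 2, 3, 4, 5}.
#' @examples
#' gradeToScore(c("A", "C", "F"))
#' @export
gradeToScore <- function(grade) {
  grade <- as.character(grade)
  bad <- !grade %in% names(GRADE_LEVELS)
  if (any(bad)) {
    stop("unknown grade(s): ", paste(unique(grade[bad]), collapse = ", "),
         " (expected A, B, C, D or F)")
  }
  unname(GRADE_LEVELS[grade])
}

#' Training and architecture configuration for the quality scorer
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4 and weight decay 1e-4, batch size 32, 200 epochs, a 10% held-out
#' validation split, and a trunk of residual stages at widths
#' 32/64/128/256. \code{stemDownsample} optionally inserts one paired
#' 2x2/stride-2 downsampling block directly after the stem (the same
#' downsampling device used between stages), which shrinks compute roughly
#' 16-fold without changing any structural property of the network.
#'
#' @param learningRate Adam learning rate (> 0).
#' @param weightDecay L2 weight decay (> 0).
#' @param batchSize mini-batch size (>= 1).
#' @param epochs training epochs (>= 1).
#' @param seed integer seed covering split, weight init and batch order.
#' @param validationFraction held-out fraction in (0, 1).
#' @param channelWidths integer vector, one width per residual stage.
#' @param blocksPerStage residual blocks per stage.
#' @param stemDownsample logical; downsample right after the stem.
#' @param fcWidth width of the hidden fully connected layer in the head.
#' @return a validated config list of class \code{"scorerConfig"}.
#' @export
scorerConfig <- function(learningRate = 1e-4, weightDecay = 1e-4,
                         batchSize = 32L, epochs = 200L, seed = 1L,
                         validationFraction = 0.10,
                         channelWidths = c(32L, 64L, 128L, 256L),
                         blocksPerStage = 2L, stemDownsample = FALSE,
                         fcWidth = 256L) {
  cfg <- list(learningRate = learningRate, weightDecay = weightDecay,
              batchSize = as.integer(batchSize), epochs = as.integer(epochs),
              seed = as.integer(seed),
              validationFraction = validationFraction,
              channelWidths = as.integer(channelWidths),
              blocksPerStage = as.integer(blocksPerStage),
              stemDownsample = isTRUE(stemDownsample),
              fcWidth = as.integer(fcWidth))
  if (!(cfg$learningRate > 0) || !(cfg$weightDecay > 0)) {
    stop("learningRate and weightDecay must be > 0")
  }
  if (cfg$batchSize < 1L) stop("batchSize must be >= 1")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (!(cfg$validationFraction > 0 && cfg$validationFraction < 1)) {
    stop("validationFraction must lie in (0, 1)")
  }
  if (!length(cfg$channelWidths) || any(cfg$channelWidths < 1L)) {
    stop("channelWidths must be positive integers")
  }
  if (cfg$stemDownsample && length(cfg$channelWidths) > 3L) {
    stop("with stemDownsample at most 3 stages fit a 210 px canvas")
  }
  class(cfg) <- "scorerConfig"
  cfg
}

#' Desk-scale scorer configuration
#'
#' A narrow configuration of the same architecture family, sized so the
#' full train-and-validate cycle on a few thousand synthetic class
#' averages runs on a single CPU in minutes: widths 6/12/24, one residual
#' block per stage, downsampling directly after the stem, a 64-unit head
#' and 30 epochs (validation loss plateaus long before the 200-epoch
#' default on desk-scale corpora). All optimizer settings are retained.
#'
#' @param seed integer seed.
#' @param epochs training epochs.
#' @return a \code{"scorerConfig"}.
#' @export
deskScorerConfig <- function(seed = 1L, epochs = 30L) {
  scorerConfig(seed = seed, epochs = epochs,
               channelWidths = c(6L, 12L, 24L), blocksPerStage = 1L,
               stemDownsample = TRUE, fcWidth = 64L)
}

.buildTrunk <- function(cfg) {
  w <- cfg$channelWidths
  if (cfg$stemDownsample) {
    # the entry point is itself a paired 2x2/stride-2 downsampling block,
    # so no wide full-resolution tensors are ever materialized; a 3x3
    # conv follows for local feature extraction
    trunk <- c(
      .downsamplePair("stem0", 1L, w[1], cmid = max(1L, w[1] %/% 2L)),
      list(
        .convLayer("stem", w[1], w[1], 3L, 1L, 1L),
        .bnreluLayer("stem.n", w[1])
      ))
  } else {
    trunk <- list(
      .convLayer("stem", 1L, w[1], 3L, 1L, 1L),
      .bnreluLayer("stem.n", w[1])
    )
  }
  for (s in seq_along(w)) {
    for (b in seq_len(cfg$blocksPerStage)) {
      trunk <- c(trunk, list(.resBlock(sprintf("s%db%d", s, b), w[s])))
    }
    if (s < length(w)) {
      trunk <- c(trunk, .downsamplePair(sprintf("down%d", s), w[s], w[s + 1]))
    }
  }
  trunk
}

#' Build an (untrained) scorer model
#'
#' Constructs the residual CNN with seeded weight initialization. The
#' trunk contains no pooling layers; every downsampling step is a pair of
#' consecutive 2x2 stride-2 convolutions, and the spatial map entering the
#' head is always adaptively average-pooled to 6 x 6 regardless of trunk
#' depth.
#'
#' @param config a [scorerConfig()].
#' @return an untrained [ScorerModel-class].
#' @export
buildScorer <- function(config = scorerConfig()) {
  if (!inherits(config, "scorerConfig")) stop("config must be a scorerConfig")
  trunk <- .buildTrunk(config)
  wLast <- config$channelWidths[length(config$channelWidths)]
  head <- list(inDim = 36L * wLast + 6L, fc = config$fcWidth)
  params <- withSeed(config$seed, .initParams(trunk, head))
  new("ScorerModel",
      params = params,
      arch = list(trunk = trunk, poolSize = 6L, head = head,
                  flatDim = 36L * wLast),
      config = unclass(config),
      featureStats = list(mean = rep(0, 6L), sd = rep(1, 6L)),
      history = data.frame(epoch = integer(), trainMSE = numeric(),
                           valMSE = numeric()),
      trained = FALSE)
}

#' Structural summary of a scorer's trunk
#'
#' Flat inventory of the trunk layers, used to assert architecture
#' constraints (absence of pooling layers, paired stride-2 downsampling).
#'
#' @param model a [ScorerModel-class].
#' @return data.frame with columns \code{id}, \code{type}, \code{k},
#'   \code{stride}.
#' @export
scorerLayerTable <- function(model) {
  rows <- list()
  walk <- function(layers) {
    for (l in layers) {
      if (l$type == "resblock") {
        rows[[length(rows) + 1L]] <<- data.frame(
          id = l$id, type = "resblock", k = NA_integer_,
          stride = NA_integer_)
        walk(l$layers)
      } else {
        rows[[length(rows) + 1L]] <<- data.frame(
          id = l$id, type = l$type,
          k = if (l$type == "conv") l$k else NA_integer_,
          stride = if (l$type == "conv") l$stride else NA_integer_)
      }
    }
  }
  walk(model@arch$trunk)
  do.call(rbind, rows)
}

# canvas images from heterogeneous inputs (matrix / CanvasImage)
.toCanvasMatrix <- function(img) {
  if (is(img, "CanvasImage")) img@pixels else resampleToCanvas(img)@pixels
}

# assemble a (210, 210, 1, N) batch tensor from a list of images
.batchTensor <- function(images, idx) {
  n <- length(idx)
  x <- array(0, dim = c(CANVAS_SIDE, CANVAS_SIDE, 1L, n))
  for (k in seq_len(n)) {
    x[, , 1L, k] <- .toCanvasMatrix(images[[idx[k]]])
  }
  x
}

.scaleMeta <- function(meta, stats) {
  # meta: n x 6; returns 6 x n scaled for the network
  t((meta - matrix(stats$mean, nrow(meta), 6L, byrow = TRUE)) /
      matrix(stats$sd, nrow(meta), 6L, byrow = TRUE))
}

.predictBatched <- function(model, images, meta, chunk = 64L) {
  n <- length(images)
  sm <- .scaleMeta(meta, model@featureStats)
  preds <- numeric(n)
  for (s in seq.int(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    x <- .batchTensor(images, idx)
    preds[idx] <- .netForward(model, x, sm[, idx, drop = FALSE],
                              training = FALSE)$pred
  }
  preds
}

#' Train the quality scorer
#'
#' Minimizes the mean squared error between predicted and labeled scores
#' with Adam at the configured learning rate and weight decay, over
#' mini-batches of the configured size. A seeded validation fraction is
#' held out before training; metadata features are z-scored with
#' training-split statistics that are stored in the model for inference.
#' The final linear layer's bias starts at the training-label mean. The
#' per-epoch train and validation MSE are recorded in the model history.
#'
#' @param corpus a labeled corpus: list with \code{images} (list of square
#'   matrices or [CanvasImage-class] objects), \code{meta} (n x 6 matrix
#'   with columns pixelSize, frcResolution, classDistribution,
#'   devMeanMass, devMedianMass, devModeMass) and \code{labels} (numeric
#'   quality scores). [makeLabeledCorpus()] produces this shape.
#' @param config a [scorerConfig()].
#' @param verbose print per-epoch losses.
#' @return a trained [ScorerModel-class].
#' @export
trainScorer <- function(corpus, config = deskScorerConfig(),
                        verbose = FALSE) {
  n <- length(corpus$labels)
  if (length(corpus$images) != n || nrow(corpus$meta) != n) {
    stop("corpus images, meta and labels must agree in length")
  }
  if (any(!is.finite(corpus$labels))) stop("labels must be finite")
  if (n < config$batchSize) {
    stop(sprintf("corpus (%d) smaller than one batch (%d)", n,
                 config$batchSize))
  }
  model <- buildScorer(config)
  out <- withSeed(config$seed + 1L, {
    nVal <- max(1L, floor(config$validationFraction * n))
    valIdx <- sample.int(n, nVal)
    trainIdx <- setdiff(seq_len(n), valIdx)

    mu <- colMeans(corpus$meta[trainIdx, , drop = FALSE])
    sdv <- apply(corpus$meta[trainIdx, , drop = FALSE], 2L, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    stats <- list(mean = as.numeric(mu), sd = as.numeric(sdv))
    model@featureStats <- stats
    model@params$weights[["head.b2"]] <- mean(corpus$labels[trainIdx])

    smAll <- .scaleMeta(corpus$meta, stats)
    adam <- .adamInit(model@params$weights)
    hist <- data.frame(epoch = integer(), trainMSE = numeric(),
                       valMSE = numeric())
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trainIdx)
      nb <- floor(length(ord) / config$batchSize)
      epLoss <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[(bi - 1L) * config$batchSize + seq_len(config$batchSize)]
        x <- .batchTensor(corpus$images, idx)
        fw <- .netForward(model, x, smAll[, idx, drop = FALSE],
                          training = TRUE)
        if (length(fw$bufUpd)) {
          model@params$buffers[names(fw$bufUpd)] <- fw$bufUpd
        }
        err <- fw$pred - corpus$labels[idx]
        epLoss <- epLoss + mean(err^2)
        bw <- .netBackward(model, fw$cache, 2 * err / length(err))
        st <- .adamStep(model@params$weights, bw$grads, adam,
                        config$learningRate, config$weightDecay)
        model@params$weights <- st$weights
        adam <- st$state
      }
      valPred <- .predictBatched(model, corpus$images[valIdx],
                                 corpus$meta[valIdx, , drop = FALSE])
      valMSE <- mean((valPred - corpus$labels[valIdx])^2)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     trainMSE = epLoss / max(nb, 1L),
                                     valMSE = valMSE))
      if (verbose) {
        message(sprintf("epoch %3d  train MSE %.4f  val MSE %.4f",
                        ep, epLoss / max(nb, 1L), valMSE))
      }
    }
    model@history <- hist
    model@trained <- TRUE
    model
  })
  out
}

#' Score the classes of a stack
#'
#' Runs the trained CNN over every class average in the stack together
#' with its six metadata features and returns one continuous quality score
#' per class, in record order. Scores are deliberately not clipped to the
#' nominal [1, 5] anchor range.
#'
#' @param model a trained [ScorerModel-class].
#' @param stack a [ClassAverageStack-class].
#' @param records class record data.frame with one row per image carrying
#'   all six metadata columns (see [classRecords()] and
#'   [addMassFeatures()]).
#' @return numeric vector of quality scores (lower = better).
#' @export
scoreClasses <- function(model, stack, records) {
  stopifnot(is(model, "ScorerModel"), is(stack, "ClassAverageStack"))
  if (!model@trained) stop("model is not trained")
  if (nrow(records) != nClasses(stack)) {
    stop("one record per class image required")
  }
  for (f in META_FEATURES) {
    if (is.null(records[[f]])) {
      stop("records missing metadata column '", f, "'")
    }
    bad <- which(!is.finite(records[[f]]))
    if (length(bad)) {
      stop(sprintf("class %d is missing metadata field '%s'",
                   records$classIndex[bad[1]], f))
    }
  }
  images <- lapply(seq_len(nClasses(stack)), function(i) classImage(stack, i))
  meta <- as.matrix(records[, META_FEATURES])
  .predictBatched(model, images, meta)
}

#' Predict scores for a labeled corpus
#'
#' @param model a trained [ScorerModel-class].
#' @param corpus corpus as in [trainScorer()].
#' @param idx optional subset of corpus indices.
#' @return numeric predictions.
#' @export
predictCorpus <- function(model, corpus, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(corpus$labels)
  .predictBatched(model, corpus$images[idx],
                  corpus$meta[idx, , drop = FALSE])
}

#' Evaluate predicted against labeled quality scores
#'
#' Reports the raw MSE on the 1-5 score scale and, after mapping scores
#' \eqn{s \to (5 - s)/4} onto [0, 1] (so 1 = best maps to 1), the MSE on
#' that scale plus a 10-bin label-vs-prediction confusion matrix.
#'
#' @param labels true quality scores.
#' @param predictions predicted quality scores.
#' @return list with \code{mse}, \code{mseBinScale}, \code{confusion}
#'   (10 x 10 matrix, rows = label bins, columns = prediction bins) and
#'   \code{n}.
#' @export
scoreEvaluation <- function(labels, predictions) {
  if (!length(labels)) stop("empty corpus")
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length")
  }
  toUnit <- function(s) pmin(1, pmax(0, (5 - s) / 4))
  toBin <- function(u) pmin(10L, floor(u * 10) + 1L)
  confusion <- matrix(0L, 10L, 10L,
                      dimnames = list(label = NULL, predicted = NULL))
  lb <- toBin(toUnit(labels))
  pb <- toBin(toUnit(predictions))
  for (k in seq_along(lb)) {
    confusion[lb[k], pb[k]] <- confusion[lb[k], pb[k]] + 1L
  }
  list(mse = mean((predictions - labels)^2),
       mseBinScale = mean((toUnit(predictions) - toUnit(labels))^2),
       confusion = confusion,
       n = length(labels))
}

#' @rdname scoreEvaluation
#' @param model a trained [ScorerModel-class].
#' @param corpus labeled corpus as in [trainScorer()].
#' @export
evaluateScorer <- function(model, corpus) {
  if (!length(corpus$labels)) stop("empty corpus")
  scoreEvaluation(corpus$labels, predictCorpus(model, corpus))
}

#' Persist / restore a scorer checkpoint
#'
#' The checkpoint is a single RDS archive holding weights, batch-norm
#' running statistics, metadata feature scaling, config and history.
#'
#' @param model a [ScorerModel-class].
#' @param path checkpoint path.
#' @return \code{path} (save) or the restored model (load).
#' @export
saveScorer <- function(model, path) {
  saveRDS(list(params = model@params, arch = model@arch,
               config = model@config, featureStats = model@featureStats,
               history = model@history, trained = model@trained),
          path)
  invisible(path)
}

#' @rdname saveScorer
#' @export
loadScorer <- function(path) {
  x <- readRDS(path)
  new("ScorerModel", params = x$params, arch = x$arch, config = x$config,
      featureStats = x$featureStats, history = x$history,
      trained = x$trained)
}
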