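# Scorer behaviour that does not need the full acceptance-scale training:
# grade mapping, structure, determinism, shapes, evaluation arithmetic.

test_that("grades map linearly onto the 1-5 score anchors", {
  expect_equal(gradeToScore("A"), 1.0)
  expect_equal(gradeToScore("C"), 3.0)
  expect_equal(gradeToScore("F"), 5.0)
  expect_equal(gradeToScore(c("B", "D")), c(2, 4))
  expect_error(gradeToScore("E"), "unknown grade")
})

test_that("config invariants are enforced", {
  expect_error(scorerConfig(learningRate = 0), "learningRate")
  expect_error(scorerConfig(batchSize = 0), "batchSize")
  expect_error(scorerConfig(validationFraction = 1), "validationFraction")
  expect_error(scorerConfig(channelWidths = integer()), "channelWidths")
})

test_that("the trunk has no pooling layers and downsamples only by paired 2x2 stride-2 convs", {
  for (cfg in list(scorerConfig(), deskScorerConfig(), tinyScorerConfig())) {
    lt <- scorerLayerTable(buildScorer(cfg))
    expect_false(any(grepl("pool", lt$type)))
    strided <- lt[!is.na(lt$stride) & lt$stride > 1L, ]
    expect_true(all(strided$k == 2L & strided$stride == 2L))
    expect_equal(nrow(strided) %% 2L, 0L)    # strided convs come in pairs
    # consecutive in the layer stream: each pair's members are adjacent
    sidx <- which(!is.na(lt$stride) & lt$stride > 1L)
    gap <- diff(sidx)[seq(1, length(sidx) - 1, by = 2)]
    expect_true(all(gap == 2L))              # conv, bn+relu, conv
  }
})

test_that("the pooled map entering the head is 6 x 6 regardless of trunk depth", {
  for (cfg in list(tinyScorerConfig(),
                   scorerConfig(channelWidths = c(4L, 6L, 8L),
                                blocksPerStage = 1L, stemDownsample = TRUE,
                                fcWidth = 8L))) {
    m <- buildScorer(cfg)
    expect_equal(m@arch$poolSize, 6L)
    wLast <- cfg$channelWidths[length(cfg$channelWidths)]
    expect_equal(m@arch$flatDim, 36L * wLast)
    expect_equal(m@arch$head$inDim, 36L * wLast + 6L)
  }
})

test_that("an untrained seeded model is deterministic and batch-shaped", {
  cfg <- tinyScorerConfig(seed = 12L)
  m1 <- buildScorer(cfg)
  m2 <- buildScorer(cfg)
  expect_identical(m1@params$weights, m2@params$weights)
  x <- array(0, dim = c(210, 210, 1, 1))
  p1 <- cryosift:::.netForward(m1, x, matrix(0, 6, 1))$pred
  p2 <- cryosift:::.netForward(m2, x, matrix(0, 6, 1))$pred
  expect_identical(p1, p2)
  xb <- array(rnorm(210 * 210 * 32), dim = c(210, 210, 1, 32))
  pb <- cryosift:::.netForward(m1, xb, matrix(0, 6, 32))$pred
  expect_length(pb, 32L)
  expect_true(all(is.finite(pb)))
})

test_that("seeded training is reproducible and learns a constant label", {
  withSeed(51, {
    corpus <- makeLabeledCorpus(160, seed = 13)
    corpus$labels <- rep(3.0, 160)
    cfg <- tinyScorerConfig(seed = 5L, epochs = 30L, batchSize = 32L)
    m1 <- trainScorer(corpus, cfg)
    h1 <- trainingHistory(m1)
    expect_equal(nrow(h1), 30L)
    expect_lt(h1$valMSE[30], 0.05)           # collapses to the label mean
    m2 <- trainScorer(corpus, cfg)
    expect_identical(trainingHistory(m2)$valMSE, h1$valMSE)
    expect_identical(m1@params$weights, m2@params$weights)
  })
})

test_that("training refuses corpora smaller than one batch", {
  corpus <- makeLabeledCorpus(10, seed = 2)
  expect_error(trainScorer(corpus, tinyScorerConfig(batchSize = 32L)),
               "smaller than one batch")
})

test_that("scoreClasses returns one unclipped finite score per class in order", {
  withSeed(52, {
    corpus <- makeLabeledCorpus(64, seed = 21)
    model <- trainScorer(corpus, tinyScorerConfig(seed = 9L, epochs = 1L,
                                                  batchSize = 32L))
    imgs <- corpus$images[1:20]
    stack <- classAverageStack(imgs, pixelSize = 1.0)
    recs <- corpus$records[1:20, ]
    recs$classDistribution <- recs$classDistribution /
      sum(recs$classDistribution)
    s1 <- scoreClasses(model, stack, recs)
    expect_length(s1, 20L)
    expect_true(all(is.finite(s1)))
    expect_identical(scoreClasses(model, stack, recs), s1)
    # missing metadata errors name the class and field
    recs2 <- recs
    recs2$frcResolution[3] <- NA_real_
    expect_error(scoreClasses(model, stack, recs2), "class 2.*frcResolution")
    # scores above 5 pass through unclipped
    m2 <- model
    m2@params$weights[["head.b2"]] <- 50
    expect_true(all(scoreClasses(m2, stack, recs) > 5))
  })
})

test_that("checkpoints round-trip through save/load", {
  corpus <- makeLabeledCorpus(40, seed = 31)
  model <- trainScorer(corpus, tinyScorerConfig(seed = 2L, epochs = 1L,
                                                batchSize = 16L))
  f <- tempfile(fileext = ".rds")
  saveScorer(model, f)
  back <- loadScorer(f)
  expect_identical(back@params$weights, model@params$weights)
  expect_identical(back@featureStats, model@featureStats)
  expect_identical(predictCorpus(back, corpus, 1:8),
                   predictCorpus(model, corpus, 1:8))
})

test_that("evaluation reports MSE and a conserving 10-bin confusion matrix", {
  labels <- c(1, 2, 3, 4, 5, 2, 3)
  ev0 <- scoreEvaluation(labels, labels)
  expect_equal(ev0$mse, 0)
  expect_equal(sum(diag(ev0$confusion)), length(labels))
  ev1 <- scoreEvaluation(labels, labels + 0.1)
  expect_equal(ev1$mse, 0.01, tolerance = 1e-12)
  withSeed(53, {
    lab <- runif(200, 1, 5)
    pred <- lab + rnorm(200, 0, 0.7)
    ev <- scoreEvaluation(lab, pred)
    binOf <- function(s) pmin(10L, floor(pmin(1, pmax(0, (5 - s) / 4)) * 10) + 1L)
    expect_equal(as.vector(rowSums(ev$confusion)),
                 as.vector(tabulate(binOf(lab), 10L)))
    expect_equal(ev$n, 200L)
  })
  expect_error(scoreEvaluation(numeric(), numeric()), "empty")
})
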