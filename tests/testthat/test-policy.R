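# Routing rules, iteration schedule, batching and full sift runs driven by
# an oracle scorer (class score = true grade).

test_that("iteration count follows the box-size tiers with inclusive boundaries", {
  expect_equal(iterationCount(150), 5L)
  expect_equal(iterationCount(250), 3L)
  expect_equal(iterationCount(350), 2L)
  expect_equal(iterationCount(199), 5L)
  expect_equal(iterationCount(200), 3L)
  expect_equal(iterationCount(300), 3L)
  expect_equal(iterationCount(301), 2L)
  expect_error(iterationCount(0), "positive")
})

test_that("classification parameter tiers match the box-size policy", {
  small <- recommendClass2DParams(150)
  expect_equal(small$tier, "small")
  expect_equal(small$maxResA, 3)
  expect_equal(small$initialUncertainty, 3)
  expect_false(small$forceMaxPosesShifts)
  expect_equal(small$onlineEMIterations, 40L)
  expect_equal(small$batchSize, 400L)
  expect_equal(recommendClass2DParams(250)$tier, "default")
  large <- recommendClass2DParams(350)
  expect_equal(large$tier, "large")
  expect_equal(large$cropToPx, 100L)
  expect_error(recommendClass2DParams(-5), "positive")
})

test_that("routing banks a seeded 70% of good scorers and discards at 4.5", {
  cfg <- policyConfig(seed = 42L)
  pt <- newParticleTable(1:1000)
  pt$score <- 2.0
  out <- routeParticles(pt, cfg, roundIndex = 1L)
  expect_equal(sum(out$state == "banked"), 700L)
  expect_equal(sum(out$state == "working"), 300L)
  expect_identical(routeParticles(pt, cfg, 1L), out)   # seeded determinism

  ptBad <- newParticleTable(1:100); ptBad$score <- 5.0
  outBad <- routeParticles(ptBad, cfg, 1L)
  expect_equal(sum(outBad$state == "discarded"), 100L)

  ptMid <- newParticleTable(1:100); ptMid$score <- 3.0
  outMid <- routeParticles(ptMid, cfg, 1L)
  expect_true(all(outMid$state == "working"))

  # boundary semantics: <= 2.5 is good, >= 4.5 is discarded
  ptEdge <- newParticleTable(1:2); ptEdge$score <- c(2.5, 4.5)
  outEdge <- routeParticles(ptEdge, cfg, 1L)
  expect_true(outEdge$state[2] == "discarded")
  expect_true(outEdge$state[1] %in% c("banked", "working"))

  expect_identical(routeParticles(newParticleTable(integer()), cfg, 1L)$state,
                   character())
  ptNA <- newParticleTable(1:3)
  expect_error(routeParticles(ptNA, cfg, 1L), "unscored")
})

test_that("banked and discarded states are permanent across rounds", {
  cfg <- policyConfig(seed = 7L)
  pt <- newParticleTable(1:200)
  pt$score <- rep(c(2.0, 5.0), 100)
  r1 <- routeParticles(pt, cfg, 1L)
  banked1 <- r1$particleId[r1$state == "banked"]
  disc1 <- r1$particleId[r1$state == "discarded"]
  r1$score[r1$state == "working"] <- 5.0
  r2 <- routeParticles(r1, cfg, 2L)
  expect_true(all(r2$state[match(banked1, r2$particleId)] == "banked"))
  expect_true(all(r2$state[match(disc1, r2$particleId)] == "discarded"))
})

test_that("final batches are nested and cumulative at <= thresholds", {
  b <- finalBatches(1:4, c(2.0, 3.0, 4.0, 4.6))
  expect_equal(b$le2.5, 1L)
  expect_equal(b$le3.5, 1:2)
  expect_equal(b$le4.5, 1:3)
  same <- finalBatches(1:5, rep(1.0, 5))
  expect_identical(same$le2.5, same$le4.5)
  empty <- finalBatches(integer(), numeric())
  expect_true(all(lengths(empty) == 0L))
  withSeed(61, {
    sc <- runif(300, 0.5, 5.5)
    bb <- finalBatches(seq_along(sc), sc)
    expect_true(all(bb$le2.5 %in% bb$le3.5))
    expect_true(all(bb$le3.5 %in% bb$le4.5))
  })
})

test_that("policy config invariants are enforced", {
  expect_error(policyConfig(acceptCutoff = 5), "below")
  expect_error(policyConfig(bankFraction = 1), "bankFraction")
  expect_error(policyConfig(finalThresholds = c(3, 2, 4)), "increasing")
})

test_that("a sift with the oracle scorer conserves particles and discards all junk", {
  cohort <- makeCohort(400, junkFraction = 0.25, seed = 19)
  backend <- syntheticBackend(cohort, kClasses = 8L, seed = 19,
                              boxSidePx = 96L)
  oracle <- function(stack, records) records$trueGrade
  res <- runSift(newParticleTable(cohort$particleId), backend, oracle,
                 boxSidePx = 150, policyConfig(seed = 19L), kClasses = 8L)
  expect_equal(res@rounds, 6L)             # 5 iterations + final pooling
  expect_equal(length(siftBatches(res)$le4.5) + length(siftDiscarded(res)),
               400L)
  # junk recall: every true-grade-5 particle lands in a grade-5 class under
  # the oracle (class medians of the quantile grouping), so none survive
  junk <- cohort$particleId[cohort$trueGrade == 5]
  expect_true(all(junk %in% siftDiscarded(res)))
  # batches nested
  expect_true(all(siftBatches(res)$le2.5 %in% siftBatches(res)$le3.5))
  expect_true(all(siftBatches(res)$le3.5 %in% siftBatches(res)$le4.5))
  # byte-identical reruns
  res2 <- runSift(newParticleTable(cohort$particleId), backend, oracle,
                  boxSidePx = 150, policyConfig(seed = 19L), kClasses = 8L)
  expect_identical(siftAudit(res2), siftAudit(res))
  expect_identical(siftBatches(res2), siftBatches(res))
})

test_that("an all-good cohort is never discarded and fills every batch", {
  cohort <- data.frame(particleId = 1:150, trueGrade = 1)
  backend <- syntheticBackend(cohort, kClasses = 5L, seed = 3,
                              boxSidePx = 96L)
  oracle <- function(stack, records) records$trueGrade
  res <- runSift(newParticleTable(cohort$particleId), backend, oracle,
                 boxSidePx = 350, policyConfig(seed = 3L), kClasses = 5L)
  expect_equal(res@rounds, 3L)             # 2 iterations + final
  expect_length(siftDiscarded(res), 0L)
  for (b in siftBatches(res)) expect_setequal(b, cohort$particleId)
})

test_that("backend failures propagate with round context", {
  cohort <- data.frame(particleId = 1:50, trueGrade = 1)
  failing <- list(classify = function(ids, params) stop("boom"))
  expect_error(
    runSift(newParticleTable(cohort$particleId), failing,
            function(stack, records) 1, boxSidePx = 150),
    "round 1.*boom")
})
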