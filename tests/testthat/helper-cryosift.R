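# Shared fixtures. Everything is generated in code at test time; the
# expensive desk-scale model is trained once per session and memoized so
# the scorer recovery, monotonicity and sift suites share it.

.fixtures <- new.env(parent = emptyenv())

# a tiny scorer configuration for structural/behavioural unit tests
tinyScorerConfig <- function(seed = 3L, epochs = 2L, batchSize = 8L) {
  scorerConfig(seed = seed, epochs = epochs, batchSize = batchSize,
               channelWidths = c(4L, 8L), blocksPerStage = 1L,
               stemDownsample = TRUE, fcWidth = 16L)
}

# the acceptance-scale corpus (n = 2000, uniform grades, seed 7)
acceptanceCorpus <- function() {
  if (is.null(.fixtures$corpus)) {
    .fixtures$corpus <- makeLabeledCorpus(2000, seed = 7L)
  }
  .fixtures$corpus
}

# the desk-scale scorer trained for 30 epochs on the acceptance corpus
acceptanceModel <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- trainScorer(acceptanceCorpus(),
                                   deskScorerConfig(seed = 7L, epochs = 30L))
  }
  .fixtures$model
}

# an oracle scorer for policy tests: returns each class's true grade
oracleScorer <- function(stack, records) {
  stopifnot(!is.null(records$trueGrade))
  records$trueGrade
}

# small cohort of latent-grade particles for sift tests
makeCohort <- function(n, junkFraction = 0.2, seed = 5L) {
  withSeed(seed, data.frame(
    particleId = seq_len(n),
    trueGrade = ifelse(runif(n) < junkFraction, 5,
                       sample(1:2, n, replace = TRUE))))
}

withSeed <- cryosift:::withSeed
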