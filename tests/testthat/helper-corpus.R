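# Shared fixtures built once per test run.
#
# The default-condition synthetic corpus (10 pairs, planted sparse
# weights, seed 7) and the structured-SVM fit on it are expensive, so
# they are computed lazily and cached for all tests that need them.

.fixtureCache <- new.env(parent = emptyenv())

acceptanceCorpus <- function() {
  if (is.null(.fixtureCache$corpus))
    .fixtureCache$corpus <- generateSynthetic(syntheticConfig(seed = 7))
  .fixtureCache$corpus
}

acceptanceFit <- function() {
  if (is.null(.fixtureCache$fit)) {
    corp <- acceptanceCorpus()
    .fixtureCache$fit <- trainModel(corp$instances,
                                    h = hyperParams(maxEpochs = 50L),
                                    seed = 7)
  }
  .fixtureCache$fit
}

acceptancePredictions <- function() {
  if (is.null(.fixtureCache$preds)) {
    corp <- acceptanceCorpus()
    fit <- acceptanceFit()
    cfg <- featureConfig()
    problems <- lapply(corp$instances, function(i)
      list(terms = computeScoreTerms(i@protein, i@rna, fit$model, cfg)))
    .fixtureCache$preds <- predictContactsBatch(problems, Xcap = 8, Ycap = 8)
  }
  .fixtureCache$preds
}

# a corpus small enough for the enumeration solver (|P| * |R| <= 20),
# used by tests that avoid the external IP backend
tinyCorpus <- function(seed = 3, nPairs = 4) {
  generateSynthetic(
    syntheticConfig(nPairs = nPairs, proteinLengthRange = c(4L, 5L),
                    rnaLengthRange = c(3L, 4L), plantedSparsity = 0.05,
                    seed = seed, Xcap = 2, Ycap = 2),
    solver = "bruteforce")
}
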