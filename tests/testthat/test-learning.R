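# Training tests run entirely on the enumeration backend with tiny
# corpora (|P| * |R| <= 20), so they exercise the full learning loop
# without the external IP solver.

test_that("AdaGrad step algebra: no-op at zero, unit first step, 1/sqrt(2) decay", {
  st <- list(w = c(k1 = 0.5), G = c(k1 = 0), eta = 1, epsilon = 0,
             maxChange = 0)
  st0 <- adagradStep(st, "k1", 0)
  expect_equal(st0$w, c(k1 = 0.5))
  expect_equal(st0$G, c(k1 = 0))

  st1 <- adagradStep(st, "k1", 2)
  # first step: eta * g / sqrt(g^2) = sign(g)
  expect_equal(unname(st1$w["k1"]), 0.5 - 1)
  st2 <- adagradStep(st1, "k1", 2)
  expect_equal(unname(st2$w["k1"] - st1$w["k1"]), -1 / sqrt(2))

  # new keys materialize at zero
  st3 <- adagradStep(st, c("k1", "k2"), c(0, 1))
  expect_equal(unname(st3$w["k2"]), -1)
})

test_that("the SVM objective reduces to C * |lambda| on an empty hinge", {
  # single 1x2 instance with empty truth and zero weights: the hinge is
  # the largest achievable loss among the feasible candidate maps
  P <- proteinRecord("p", "M", "H")
  R <- rnaRecord("r", "AC", "..")
  inst <- trainingInstance(P, R, contactMap(nResidues = 1, nBases = 2))
  h <- hyperParams()
  got <- svmObjective(list(inst), modelWeights(), h, solver = "bruteforce")
  # feasible maps on 1x2: empty, {(1,1),(1,2)} (single contacts leave an
  # isolated base); exhaustive max of the loss
  best <- 0
  for (zHat in allMaps(1, 2)) {
    if (length(checkContactConstraints(zHat, h@Xcap, h@Ycap)) > 0) next
    best <- max(best, contactLoss(inst@map, zHat, h))
  }
  expect_gt(best, 0)
  expect_equal(got, best, tolerance = 1e-9)

  # nonzero weights add exactly the l1 term when data are absent from
  # the feature support
  model <- modelWeights(c("residue-3mer\tWWW" = 2, "residue-3mer\tYYY" = -1))
  got2 <- svmObjective(list(inst), model, h, solver = "bruteforce")
  expect_equal(got2 - got >= 0, TRUE)
  expect_equal(got2, best + h@C * 3 +
                 max(0, 0), tolerance = 1e-6)
})

test_that("the per-instance subgradient matches finite differences of the hinge", {
  set.seed(91)
  corp <- tinyCorpus(seed = 5, nPairs = 1)
  inst <- corp$instances[[1]]
  cfg <- featureConfig()
  h <- hyperParams(Xcap = 2, Ycap = 2)
  # random sparse weights over realizable keys
  full <- contactMap(cbind(rep(seq_len(nResidues(inst)), each = nBases(inst)),
                           rep(seq_len(nBases(inst)), nResidues(inst))),
                     nResidues(inst), nBases(inst))
  keys <- names(fullFeatures(inst@protein, inst@rna, full, cfg))
  w0 <- stats::setNames(stats::rnorm(length(keys), sd = 0.3), keys)
  model0 <- modelWeights(w0)

  hinge <- function(w) {
    m <- modelWeights(w)
    tm <- computeScoreTerms(inst@protein, inst@rna, m, cfg)
    aug <- lossAugment(tm, inst@map, h)
    sol <- predictBruteForce(aug, h@Xcap, h@Ycap)
    sol$objective - scoreContactMap(inst@protein, inst@rna, inst@map, m, cfg)
  }

  tm <- computeScoreTerms(inst@protein, inst@rna, model0, cfg)
  aug <- lossAugment(tm, inst@map, h)
  zHat <- predictBruteForce(aug, h@Xcap, h@Ycap)$map
  phiHat <- fullFeatures(inst@protein, inst@rna, zHat, cfg)
  phiTrue <- fullFeatures(inst@protein, inst@rna, inst@map, cfg)

  for (rep in 1:5) {
    d <- stats::setNames(stats::rnorm(length(keys)), keys)
    gDotD <- sum(d[names(phiHat)] * phiHat, na.rm = TRUE) -
      sum(d[names(phiTrue)] * phiTrue, na.rm = TRUE)
    t <- 1e-6
    fd <- (hinge(w0 + t * d) - hinge(w0)) / t
    expect_equal(fd, gDotD, tolerance = 1e-3)
  }
})

test_that("training is deterministic and drives the hinge down on separable data", {
  corp <- tinyCorpus(seed = 3)
  h <- hyperParams(Xcap = 2, Ycap = 2, maxEpochs = 25L)
  fit1 <- trainModel(corp$instances, h = h, seed = 11, solver = "bruteforce")
  fit2 <- trainModel(corp$instances, h = h, seed = 11, solver = "bruteforce")
  expect_identical(featureWeights(fit1$model), featureWeights(fit2$model))
  expect_lt(fit1$history$hinge[nrow(fit1$history)], fit1$history$hinge[1])

  # objective at the fitted weights is below the objective at zero
  o0 <- svmObjective(corp$instances, modelWeights(), h, solver = "bruteforce")
  o1 <- svmObjective(corp$instances, fit1$model, h, solver = "bruteforce")
  expect_lt(o1, o0)

  # the fitted model reproduces its training labels
  cfg <- featureConfig()
  for (inst in corp$instances) {
    tm <- computeScoreTerms(inst@protein, inst@rna, fit1$model, cfg)
    pred <- predictBruteForce(tm, h@Xcap, h@Ycap)$map
    expect_identical(contacts(pred), contacts(inst@map))
  }
})

test_that("a huge l1 weight collapses the model toward zero", {
  # With the plain l1 subgradient of the update rule (sgn(0) = 0),
  # weights oscillate around zero with AdaGrad-damped amplitude rather
  # than landing exactly on it, so the collapse shows up as uniformly
  # tiny weights and a near-zero optimal decoding objective (an exactly
  # empty argmax would require the proximal/FOBOS step, which the
  # learner deliberately does not use).
  corp <- tinyCorpus(seed = 9, nPairs = 2)
  h <- hyperParams(C = 50, Xcap = 2, Ycap = 2, maxEpochs = 30L)
  fit <- trainModel(corp$instances, h = h, seed = 2, solver = "bruteforce")
  smallW <- featureWeights(fit$model)
  hSmallC <- hyperParams(Xcap = 2, Ycap = 2, maxEpochs = 30L)
  ref <- trainModel(corp$instances, h = hSmallC, seed = 2,
                    solver = "bruteforce")
  expect_lt(max(abs(smallW)), 0.4)
  expect_lt(max(abs(smallW)), max(abs(featureWeights(ref$model))) / 2)
  cfg <- featureConfig()
  for (inst in corp$instances) {
    tm <- computeScoreTerms(inst@protein, inst@rna, fit$model, cfg)
    res <- predictBruteForce(tm, h@Xcap, h@Ycap)
    tmRef <- computeScoreTerms(inst@protein, inst@rna, ref$model, cfg)
    refObj <- predictBruteForce(tmRef, 2, 2)$objective
    expect_lt(res$objective, refObj / 3)
  }
})

test_that("training rejects empty corpora and infeasible gold maps", {
  expect_error(trainModel(list(), hyperParams()), "empty")
  P <- randomProteinRecord("badpair", 2)
  R <- randomRnaRecord("r", 3)
  # two contacts on one residue violate an Xcap of 1
  inst <- trainingInstance(P, R, contactMap(rbind(c(1, 1), c(1, 2)), 2, 3))
  expect_error(trainModel(list(inst), hyperParams(Xcap = 1, Ycap = 8),
                          solver = "bruteforce"),
               "badpair.*infeasible|infeasible.*badpair")
})
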