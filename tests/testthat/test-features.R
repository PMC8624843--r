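test_that("windows are centered and padded at boundaries", {
  expect_equal(kmerWindow("MKV", 2, 3), "MKV")
  expect_equal(kmerWindow("MKV", 1, 3), "^MK")
  expect_equal(kmerWindow("A", 1, 5), "^^A^^")
  expect_equal(kmerWindow("ACGU", 1:4, 3), c("^AC", "ACG", "CGU", "GU^"))
  expect_error(kmerWindow("MKV", 2, 4), "odd")
})

test_that("simplified alphabets follow the published groups", {
  expect_equal(simplifyAlphabet("LVC", "g10"), "LLC")
  expect_equal(simplifyAlphabet("LVC", "g4"), "LLL")
  expect_equal(simplifyAlphabet("", "g10"), "")
  # every group maps to its first printed letter
  expect_equal(simplifyAlphabet("ACDEFGHIKLMNPQRSTVWY", "g10"),
               "ACEEFGHLKLLEPEKSSLFF")
  expect_equal(simplifyAlphabet("ACDEFGHIKLMNPQRSTVWY", "g4"),
               "ALEEFAELELLEAEEAALFF")
  expect_error(simplifyAlphabet("AXB", "g10"), "illegal character")
})

test_that("residue features fire one key per configured row at each bound residue", {
  P <- proteinRecord("p", "MKV", "HHH")
  phi <- residueFeatures(P, c(0, 1, 0))
  expect_equal(sum(phi), 8)  # 8 residue feature rows
  expected <- c("residue-3mer\tMKV", "residue-5mer\t^MKV^",
                "sa10-5mer\t^LKL^", "sa10-7mer\t^^LKL^^",
                "sa4-5mer\t^LEL^", "sa4-7mer\t^^LEL^^",
                "protss-3mer\tHHH", "protss-5mer\t^HHH^")
  expect_setequal(names(phi), expected)
  expect_true(all(phi == 1))

  expect_equal(length(residueFeatures(P, c(0, 0, 0))), 0L)

  # identical windows accumulate counts
  P2 <- proteinRecord("p2", "AAAAA", "HHHHH")
  phi2 <- residueFeatures(P2, c(0, 1, 1, 1, 0))
  expect_equal(unname(phi2["residue-3mer\tAAA"]), 3)
})

test_that("base features mirror the residue construction over RNA tracks", {
  R <- rnaRecord("r", "ACG", "...")
  phi <- baseFeatures(R, c(1, 0, 0))
  expect_equal(phi, c("base-3mer\t^AC" = 1, "base-5mer\t^^ACG" = 1,
                      "rnass-3mer\t^EE" = 1, "rnass-5mer\t^^EEE" = 1)[names(phi)])
  expect_equal(length(baseFeatures(R, c(0, 0, 0))), 0L)
})

test_that("contact features pair equal-length windows per contact", {
  P <- proteinRecord("p", "MKV", "HHH")
  R <- rnaRecord("r", "ACG", "...")
  z <- contactMap(cbind(2, 2), 3, 3)
  phi <- contactFeatures(P, R, z)
  expect_equal(length(phi), 12L)  # 12 contact rows
  expect_equal(unname(phi["contact:res3xbase3\tMKV\tACG"]), 1)
  expect_equal(unname(phi["contact:protss3xrnass3\tHHH\tEEE"]), 1)
  expect_equal(unname(phi["contact:sa103xbase3\tLKL\tACG"]), 1)
  expect_equal(unname(phi["contact:sa45xrnass5\t^LEL^\t^EEE^"]), 1)
  expect_equal(length(contactFeatures(P, R, contactMap(nResidues = 3, nBases = 3))), 0L)
})

test_that("feature count mass equals sites times configured rows", {
  set.seed(17)
  cfg <- featureConfig()
  for (rep in 1:10) {
    P <- randomProteinRecord("p", sample(3:10, 1))
    R <- randomRnaRecord("r", sample(3:10, 1))
    z <- randomConsistentMap(nchar(P@sequence), nchar(R@sequence))
    ind <- bindingIndicators(z)
    expect_equal(sum(residueFeatures(P, ind$x, cfg)),
                 sum(ind$x) * nrow(cfg@residueRows))
    expect_equal(sum(baseFeatures(R, ind$y, cfg)),
                 sum(ind$y) * nrow(cfg@baseRows))
    expect_equal(sum(contactFeatures(P, R, z, cfg)),
                 nrow(contacts(z)) * nrow(cfg@contactRows))
    # full vector = concatenation over disjoint key spaces
    phi <- fullFeatures(P, R, z, cfg)
    expect_equal(sum(phi), sum(ind$x) * nrow(cfg@residueRows) +
                   sum(ind$y) * nrow(cfg@baseRows) +
                   nrow(contacts(z)) * nrow(cfg@contactRows))
    expect_false(anyDuplicated(names(phi)) > 0)
  }
})

test_that("contact order does not change the feature vector", {
  P <- randomProteinRecord("p", 6)
  R <- randomRnaRecord("r", 6)
  cm <- rbind(c(1, 2), c(3, 3), c(5, 2), c(2, 6))
  a <- fullFeatures(P, R, contactMap(cm, 6, 6))
  b <- fullFeatures(P, R, contactMap(cm[c(3, 1, 4, 2), ], 6, 6))
  expect_identical(a, b)
})

test_that("scoring is the sparse inner product with missing keys at zero", {
  P <- proteinRecord("p", "MKV", "HHH")
  R <- rnaRecord("r", "ACG", "...")
  z <- contactMap(cbind(2, 1), 3, 3)
  expect_equal(scoreContactMap(P, R, z, modelWeights()), 0)
  expect_equal(scoreContactMap(P, R, contactMap(nResidues = 3, nBases = 3),
                               modelWeights(c("residue-3mer\tMKV" = 2))), 0)
  expect_equal(scoreContactMap(P, R, z,
                               modelWeights(c("residue-3mer\tMKV" = 2))), 2)
})

test_that("precomputed score terms locate weights at the right positions", {
  R <- rnaRecord("r", "ACG", "...")
  P <- proteinRecord("p", "MKV", "HHH")
  model <- modelWeights(c("base-3mer\t^AC" = 1.5))
  tm <- computeScoreTerms(P, R, model)
  expect_equal(tm@v, c(1.5, 0, 0))
  expect_equal(tm@u, c(0, 0, 0))
  expect_true(all(tm@w == 0))
  expect_equal(tm@offset, 0)
})

test_that("feature-space score equals the precomputed linear form", {
  set.seed(23)
  cfg <- featureConfig()
  for (rep in 1:12) {
    P <- randomProteinRecord("p", sample(3:8, 1))
    R <- randomRnaRecord("r", sample(3:8, 1))
    # random weights over keys realizable in this pair, plus noise keys
    full <- contactMap(cbind(rep(seq_len(nchar(P@sequence)), each = nchar(R@sequence)),
                             rep(seq_len(nchar(R@sequence)), nchar(P@sequence))),
                       nchar(P@sequence), nchar(R@sequence))
    keys <- names(fullFeatures(P, R, full, cfg))
    sel <- sample(keys, min(length(keys), 60))
    model <- modelWeights(stats::setNames(stats::rnorm(length(sel)), sel))
    tm <- computeScoreTerms(P, R, model, cfg)
    for (rep2 in 1:5) {
      z <- randomConsistentMap(nchar(P@sequence), nchar(R@sequence))
      expect_equal(scoreContactMap(P, R, z, model, cfg),
                   objectiveByHand(tm, z), tolerance = 1e-12)
    }
  }
})
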