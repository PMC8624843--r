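test_that("coordinate contacts respect the distance threshold strictly", {
  pa <- data.frame(index = 1L, atom = "CA", x = 0, y = 0, z = 0)
  ra <- data.frame(index = 1L, atom = "P", x = 0, y = 0, z = 3.9)
  expect_equal(contacts(contactsFromCoordinates(pa, ra, 4.0)), cbind(1L, 1L))
  ra$z <- 4.1
  expect_equal(nrow(contacts(contactsFromCoordinates(pa, ra, 4.0))), 0L)

  pa2 <- data.frame(index = c(1L, 2L), atom = c("CA", "CB"),
                    x = c(0, 0), y = c(0, 0), z = c(10, 1))
  ra2 <- data.frame(index = 1L, atom = "P", x = 0, y = 0, z = 0)
  m <- contactsFromCoordinates(pa2, ra2, 4.0)
  expect_equal(contacts(m), cbind(2L, 1L))
  expect_error(contactsFromCoordinates(pa2[0, ], ra2), "empty atom list")
})

test_that("coordinate contacts are invariant to joint rigid motion", {
  set.seed(55)
  pa <- data.frame(index = rep(1:3, each = 4), atom = "X",
                   x = rnorm(12, sd = 3), y = rnorm(12, sd = 3),
                   z = rnorm(12, sd = 3))
  ra <- data.frame(index = rep(1:2, each = 3), atom = "X",
                   x = rnorm(6, sd = 3), y = rnorm(6, sd = 3),
                   z = rnorm(6, sd = 3))
  base <- contactsFromCoordinates(pa, ra, 4.0, nResidues = 3, nBases = 2)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  shift <- c(5, -2, 9)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% rot
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  moved <- contactsFromCoordinates(move(pa), move(ra), 4.0,
                                   nResidues = 3, nBases = 2)
  expect_identical(contacts(moved), contacts(base))
})

test_that("sampled dot-brackets are well-formed at every length", {
  set.seed(66)
  for (rep in 1:60) {
    n <- sample(3:30, 1)
    s <- sampleDotBracket(n)
    expect_equal(nchar(s), n)
    pairs <- parseDotBracket(s)
    # pairs balance exactly with the bracket counts
    expect_equal(nrow(pairs), sum(strsplit(s, "")[[1]] == "("))
    # profile derivation succeeds on every sampled structure
    expect_equal(nchar(rnaProfile(s)), n)
  }
})

test_that("synthetic corpora are deterministic and self-consistent", {
  a <- tinyCorpus(seed = 13)
  b <- tinyCorpus(seed = 13)
  expect_identical(featureWeights(a$planted), featureWeights(b$planted))
  for (k in seq_along(a$instances)) {
    expect_identical(a$instances[[k]]@protein@sequence,
                     b$instances[[k]]@protein@sequence)
    expect_identical(a$instances[[k]]@rna@dotbracket,
                     b$instances[[k]]@rna@dotbracket)
    expect_identical(contacts(a$instances[[k]]@map),
                     contacts(b$instances[[k]]@map))
  }
  # labels are feasible and reproduced exactly by decoding under the
  # planted weights
  cfg <- featureConfig()
  for (inst in a$instances) {
    expect_length(checkContactConstraints(inst@map, 2, 2), 0)
    tm <- computeScoreTerms(inst@protein, inst@rna, a$planted, cfg)
    again <- predictBruteForce(tm, Xcap = 2, Ycap = 2)
    expect_identical(contacts(again$map), contacts(inst@map))
  }
})

test_that("uniformly negative weights label every pair with the empty map", {
  corp <- tinyCorpus(seed = 21, nPairs = 2)
  cfg <- featureConfig()
  for (inst in corp$instances) {
    full <- contactMap(cbind(rep(seq_len(nResidues(inst)), each = nBases(inst)),
                             rep(seq_len(nBases(inst)), nResidues(inst))),
                       nResidues(inst), nBases(inst))
    keys <- names(fullFeatures(inst@protein, inst@rna, full, cfg))
    neg <- modelWeights(stats::setNames(rep(-1, length(keys)), keys))
    tm <- computeScoreTerms(inst@protein, inst@rna, neg, cfg)
    res <- predictBruteForce(tm, 2, 2)
    expect_equal(nrow(contacts(res$map)), 0L)
    expect_equal(res$objective, 0)
  }
})

test_that("corpus serialization round-trips through the plain-text formats", {
  corp <- tinyCorpus(seed = 17, nPairs = 3)
  dir <- withr::local_tempdir()
  writeCorpus(corp$instances, dir)
  back <- readCorpus(dir)
  expect_length(back, 3L)
  for (k in 1:3) {
    expect_identical(back[[k]]@protein@sequence,
                     corp$instances[[k]]@protein@sequence)
    expect_identical(back[[k]]@protein@ss8, corp$instances[[k]]@protein@ss8)
    expect_identical(back[[k]]@rna@dotbracket,
                     corp$instances[[k]]@rna@dotbracket)
    expect_identical(back[[k]]@rna@profile, corp$instances[[k]]@rna@profile)
    expect_identical(contacts(back[[k]]@map), contacts(corp$instances[[k]]@map))
  }
})

# minimal PDB writer for fixtures: one atom per line, standard columns
writePdbFixture <- function(path, rows) {
  lines <- vapply(seq_len(nrow(rows)), function(r) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r, rows$atom[r], "", rows$resid[r], rows$chain[r], rows$resno[r],
            "", rows$x[r], rows$y[r], rows$z[r], 1.0, 0.0, rows$elem[r])
  }, character(1))
  writeLines(c(lines, "END"), path)
}

test_that("PDB import extracts sequences and the 4 Angstrom contact map", {
  rows <- rbind(
    data.frame(atom = "CA", resid = "ALA", chain = "A", resno = 1,
               x = 0, y = 0, z = 0, elem = "C"),
    data.frame(atom = "CB", resid = "GLY", chain = "A", resno = 2,
               x = 0, y = 0, z = 8, elem = "C"),
    data.frame(atom = "H1", resid = "GLY", chain = "A", resno = 2,
               x = 0, y = 0, z = 3.0, elem = "H"),   # hydrogen: excluded
    data.frame(atom = "P", resid = "A", chain = "B", resno = 1,
               x = 0, y = 0, z = 3.9, elem = "P"),
    data.frame(atom = "O2'", resid = "C", chain = "B", resno = 2,
               x = 0, y = 0, z = 12.1, elem = "O"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(f, rows)
  sk <- pdbToInstances(f, "A", "B")
  expect_equal(sk$proteinSequence, "AG")
  expect_equal(sk$rnaSequence, "AC")
  # residue 1 - base 1 at 3.9 in; residue 2 - base 2 at 4.1 out; the
  # 3.0 A hydrogen must not create a contact to base 1
  expect_equal(contacts(sk$map), cbind(1L, 1L))
  expect_error(pdbToInstances(f, "Z", "B"), "chain 'Z' not found")
})

test_that("PDB import skips non-standard residues with a warning", {
  rows <- rbind(
    data.frame(atom = "CA", resid = "ALA", chain = "A", resno = 1,
               x = 0, y = 0, z = 0, elem = "C"),
    data.frame(atom = "CA", resid = "MSE", chain = "A", resno = 2,
               x = 0, y = 0, z = 2, elem = "C"),
    data.frame(atom = "CA", resid = "GLY", chain = "A", resno = 3,
               x = 0, y = 0, z = 4, elem = "C"),
    data.frame(atom = "P", resid = "A", chain = "B", resno = 1,
               x = 0, y = 0, z = 6, elem = "P"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbFixture(f, rows)
  expect_warning(sk <- pdbToInstances(f, "A", "B"), "non-standard")
  expect_equal(sk$proteinSequence, "AG")        # indices compacted
  expect_equal(contacts(sk$map), cbind(2L, 1L)) # GLY at compacted index 2
})
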