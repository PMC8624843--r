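## Dataset construction: contact maps from 3D coordinates by a
## heavy-atom distance criterion, PDB import, corpus serialization,
## and a fully synthetic labeled-corpus generator with planted weights.

#' Contact map from atomic coordinates by a distance cutoff
#'
#' A residue i and base j are in contact iff the minimum Euclidean
#' distance over their atom pairs is at most `cutoff` (default 4.0
#' Angstroms, the van der Waals contact criterion; hydrogen-bond
#' distances of 3.5 A fall inside it).  The caller is expected to have
#' excluded hydrogen atoms.
#'
#' @param proteinAtoms,rnaAtoms data.frames with columns `index`
#'   (1-based residue/base index), `atom` (atom name) and `x`, `y`, `z`
#'   (coordinates in Angstroms).
#' @param cutoff distance threshold in Angstroms.
#' @param nResidues,nBases map dimensions; default the maximum index
#'   present.
#' @return A [ContactMap-class].
#' @export
contactsFromCoordinates <- function(proteinAtoms, rnaAtoms, cutoff = 4.0,
                                    nResidues = NULL, nBases = NULL) {
  need <- c("index", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(proteinAtoms)), all(need %in% names(rnaAtoms)))
  if (nrow(proteinAtoms) == 0L || nrow(rnaAtoms) == 0L)
    .dataError("empty atom list: both molecules need at least one heavy atom")
  if (is.null(nResidues)) nResidues <- max(proteinAtoms$index)
  if (is.null(nBases)) nBases <- max(rnaAtoms$index)
  A <- as.matrix(proteinAtoms[, c("x", "y", "z")])
  B <- as.matrix(rnaAtoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(contactMap(nResidues = nResidues, nBases = nBases))
  contactMap(cbind(proteinAtoms$index[hit[, 1L]], rnaAtoms$index[hit[, 2L]]),
             nResidues, nBases)
}

## ---- synthetic corpus ----

## 8-state secondary-structure sampler: first-order Markov chain with a
## high self-transition so states come in runs, as real SS8 strings do
.sampleSs8 <- function(n, stay = 0.75) {
  states <- SS8_ALPHABET
  out <- character(n)
  out[1L] <- sample(states, 1L)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- if (stats::runif(1) < stay) out[i]
                   else sample(setdiff(states, out[i]), 1L)
  }
  paste(out, collapse = "")
}

## Recursive well-formed dot-bracket sampler.  Stems are >= 3 bp;
## stem-loops need >= 9 nt (3 bp + >= 3 nt hairpin); a multibranch loop
## (>= 20 nt interior) closes two stem-loops.  Bulges/internal loops
## split a helix with probability 1/2 when there is room, so that all
## six profile states occur with positive probability across a corpus.
.sampleStemLoop <- function(m) {
  stopifnot(m >= 9L)
  hmax <- (m - 3L) %/% 2L                # keep >= 3 nt inside the helix
  h <- if (m >= 24L && stats::runif(1) < 0.8) 3L   # leave room to branch
       else 3L + min(stats::rbinom(1L, 3L, 0.2), hmax - 3L)
  interior <- m - 2L * h
  paste0(strrep("(", h), .sampleInterior(interior), strrep(")", h))
}

.sampleInterior <- function(m) {
  stopifnot(m >= 3L)
  if (m >= 18L && stats::runif(1) < 0.65) {
    ## multibranch: two stem-loops plus unpaired spacers
    spare <- m - 18L
    alloc <- if (spare > 0L)
      as.integer(stats::rmultinom(1L, spare, rep(1, 5L))) else integer(5L)
    return(paste0(strrep(".", alloc[1L]),
                  .sampleStemLoop(9L + alloc[2L]),
                  strrep(".", alloc[3L]),
                  .sampleStemLoop(9L + alloc[4L]),
                  strrep(".", alloc[5L])))
  }
  if (m >= 10L && stats::runif(1) < 0.6) {
    ## bulge (one-sided gap) or internal loop (two-sided gap) around an
    ## inner helix
    g <- sample.int(min(5L, m - 9L), 1L)
    if (g >= 2L && stats::runif(1) < 0.6) {
      gl <- sample.int(g - 1L, 1L)
      gr <- g - gl
    } else if (stats::runif(1) < 0.5) {
      gl <- g; gr <- 0L
    } else {
      gl <- 0L; gr <- g
    }
    return(paste0(strrep(".", gl), .sampleStemLoop(m - g), strrep(".", gr)))
  }
  strrep(".", m)                         # hairpin loop
}

#' Sample a random well-formed dot-bracket string
#'
#' Places up to three stem-loop trees separated by external unpaired
#' stretches; sequences shorter than 9 nt are left unpaired.
#'
#' @param n RNA length.
#' @return a balanced dot-bracket string of length `n`.
#' @export
sampleDotBracket <- function(n) {
  if (n < 9L) return(strrep(".", n))
  if (n >= 24L && stats::runif(1) < 0.5) {
    ## deep mode: one stem-loop spanning nearly the whole sequence, the
    ## only way multibranch loops fit at these lengths
    e <- sample.int(4L, 1L) - 1L
    el <- sample.int(e + 1L, 1L) - 1L
    return(paste0(strrep(".", el), .sampleStemLoop(n - e),
                  strrep(".", e - el)))
  }
  kmax <- min(3L, n %/% 9L)
  k <- sample.int(kmax, 1L, prob = 1 / seq_len(kmax))   # favor fewer stems
  spare <- n - 9L * k
  ## distribute the spare positions over k stems and k + 1 gaps, with
  ## stems favored so deep structures (multibranch loops) are reachable
  slots <- 2L * k + 1L
  wts <- rep(1, slots)
  wts[2L * seq_len(k)] <- 6
  alloc <- if (spare > 0L) as.integer(stats::rmultinom(1L, spare, wts))
           else integer(slots)
  parts <- character(0)
  for (t in seq_len(k)) {
    parts <- c(parts, strrep(".", alloc[2L * t - 1L]),
               .sampleStemLoop(9L + alloc[2L * t]))
  }
  paste0(paste(parts, collapse = ""), strrep(".", alloc[slots]))
}

## every feature key realizable in a corpus: the keys of the all-ones
## contact map of each pair
.realizableKeys <- function(instances, config) {
  keys <- lapply(instances, function(inst) {
    nP <- nchar(inst@protein@sequence)
    nR <- nchar(inst@rna@sequence)
    full <- contactMap(cbind(rep(seq_len(nP), each = nR),
                             rep(seq_len(nR), times = nP)), nP, nR)
    names(fullFeatures(inst@protein, inst@rna, full, config))
  })
  unique(unlist(keys, use.names = FALSE))
}

#' Generate a fully synthetic labeled corpus from planted weights
#'
#' Emulates the inputs of the real pipeline: random protein sequences
#' with Markov-sampled 8-state structure strings, random RNA sequences
#' with sampled stem-loop dot-brackets (and derived profiles), sparse
#' planted weights over the feature keys realizable in the corpus, and
#' labels obtained by exact IP decoding under the planted weights and
#' the configured caps.  Deterministic given `config@seed`.  Labels
#' satisfy the decoding constraints by construction, so the corpus is
#' always feasible training input.
#'
#' @param config a [SyntheticConfig-class].
#' @param featureCfg a [FeatureConfig-class].
#' @param solver IP backend used for labeling.
#' @return list with `instances` (list of [TrainingInstance-class]),
#'   `planted` (the planted [ModelWeights-class]) and `config`.
#' @export
generateSynthetic <- function(config = syntheticConfig(),
                              featureCfg = featureConfig(),
                              solver = getOption("PRIcontact.solver", "highs")) {
  stopifnot(is(config, "SyntheticConfig"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(config@seed)

  sampleLen <- function(range) {
    if (range[1L] == range[2L]) range[1L]
    else sample(seq(range[1L], range[2L]), 1L)
  }
  skeletons <- lapply(seq_len(config@nPairs), function(i) {
    id <- sprintf("synth%03d", i)
    nP <- sampleLen(config@proteinLengthRange)
    nR <- sampleLen(config@rnaLengthRange)
    prot <- proteinRecord(id,
                          paste(sample(AA_ALPHABET, nP, replace = TRUE),
                                collapse = ""),
                          .sampleSs8(nP))
    rna <- rnaRecord(id,
                     paste(sample(RNA_ALPHABET, nR, replace = TRUE),
                           collapse = ""),
                     sampleDotBracket(nR))
    trainingInstance(prot, rna, contactMap(nResidues = nP, nBases = nR))
  })

  keys <- sort(.realizableKeys(skeletons, featureCfg))
  nPlant <- max(1L, round(config@plantedSparsity * length(keys)))
  sel <- sample(keys, nPlant)
  planted <- modelWeights(stats::setNames(
    stats::rnorm(nPlant, sd = config@plantedScale), sel))
  if (length(planted) == 0L)
    warning("all planted weights are zero; labels will be empty maps")

  problems <- lapply(skeletons, function(inst)
    list(terms = computeScoreTerms(inst@protein, inst@rna, planted, featureCfg)))
  sols <- predictContactsBatch(problems, Xcap = config@Xcap,
                               Ycap = config@Ycap, solver = solver)
  instances <- mapply(function(inst, sol)
    trainingInstance(inst@protein, inst@rna, sol$map),
    skeletons, sols, SIMPLIFY = FALSE)
  list(instances = instances, planted = planted, config = config)
}

## ---- PDB import ----

#' Build a training-instance skeleton from a PDB complex
#'
#' Extracts one protein chain and one RNA chain from a PDB file,
#' reconstructs their sequences in author order, and derives the
#' contact map by the heavy-atom distance criterion (default 4.0 A).
#' Non-standard residues and nucleotides are skipped with a warning and
#' indices are compacted.  Secondary-structure strings are left to
#' external predictors, so the return value is a skeleton, not a
#' [TrainingInstance-class].
#'
#' @param pdbFile path to a PDB file (ATOM records).
#' @param proteinChain,rnaChain chain identifiers.
#' @param cutoff contact distance threshold in Angstroms.
#' @return list with `proteinId`, `proteinSequence`, `rnaId`,
#'   `rnaSequence` and `map` (a [ContactMap-class]).
#' @export
pdbToInstances <- function(pdbFile, proteinChain, rnaChain, cutoff = 4.0) {
  pdb <- bio3d::read.pdb(pdbFile)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]

  extractChain <- function(chainId, residueNames, what) {
    sel <- atoms[atoms$chain == chainId, , drop = FALSE]
    if (nrow(sel) == 0L) .dataError(sprintf("chain '%s' not found", chainId))
    resKey <- paste(sel$resno, ifelse(is.na(sel$insert), "", sel$insert))
    order <- unique(resKey)
    resid1 <- vapply(order, function(k) sel$resid[resKey == k][1L], character(1))
    keep <- resid1 %in% residueNames
    if (any(!keep))
      warning(sprintf("%s chain '%s': skipping %d non-standard residues (%s)",
                      what, chainId, sum(!keep),
                      paste(unique(resid1[!keep]), collapse = ",")))
    order <- order[keep]
    if (length(order) == 0L)
      .dataError(sprintf("chain '%s' has no standard %s residues", chainId, what))
    idx <- match(resKey, order)           # NA for skipped residues
    heavy <- !grepl("^H", sel$elety) &
      (is.na(sel$elesy) | toupper(sel$elesy) != "H")
    use <- heavy & !is.na(idx)
    if (!any(use))
      .dataError(sprintf("chain '%s' has no heavy atoms", chainId))
    list(atoms = data.frame(index = idx[use], atom = sel$elety[use],
                            x = sel$x[use], y = sel$y[use], z = sel$z[use],
                            stringsAsFactors = FALSE),
         resid = resid1[keep])
  }

  aaNames <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
               "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
               "THR", "VAL", "TRP", "TYR")
  prot <- extractChain(proteinChain, aaNames, "protein")
  rna <- extractChain(rnaChain, c("A", "C", "G", "U"), "RNA")
  protSeq <- paste(bio3d::aa321(prot$resid), collapse = "")
  rnaSeq <- paste(rna$resid, collapse = "")
  map <- contactsFromCoordinates(prot$atoms, rna$atoms, cutoff = cutoff,
                                 nResidues = nchar(protSeq),
                                 nBases = nchar(rnaSeq))
  list(proteinId = proteinChain, proteinSequence = protSeq,
       rnaId = rnaChain, rnaSequence = rnaSeq, map = map)
}

## ---- corpus serialization ----

#' Write / read a corpus as FASTA + annotations + contact TSVs
#'
#' Layout under `dir`: `proteins.fasta`, `rnas.fasta`, `ss8.tsv`,
#' `dotbracket.tsv` (both `id<TAB>string`), and one two-column contact
#' TSV per pair under `contacts/<id>.tsv`.  Proteins and RNAs of a pair
#' share the same record id.
#'
#' @param instances list of [TrainingInstance-class] objects.
#' @param dir corpus directory (created if missing).
#' @return `dir`, invisibly (`writeCorpus`); list of
#'   [TrainingInstance-class] (`readCorpus`).
#' @export
writeCorpus <- function(instances, dir) {
  dir.create(file.path(dir, "contacts"), recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(instances, function(i) i@protein@id, character(1))
  if (anyDuplicated(ids)) .dataError("duplicate instance ids in corpus")
  writeLines(unlist(lapply(instances, function(i)
    c(paste0(">", i@protein@id), i@protein@sequence))),
    file.path(dir, "proteins.fasta"))
  writeLines(unlist(lapply(instances, function(i)
    c(paste0(">", i@rna@id), i@rna@sequence))),
    file.path(dir, "rnas.fasta"))
  writeAnnotations(stats::setNames(
    vapply(instances, function(i) i@protein@ss8, character(1)), ids),
    file.path(dir, "ss8.tsv"))
  writeAnnotations(stats::setNames(
    vapply(instances, function(i) i@rna@dotbracket, character(1)), ids),
    file.path(dir, "dotbracket.tsv"))
  for (i in instances)
    writeContactMap(i@map, file.path(dir, "contacts", paste0(i@protein@id, ".tsv")))
  invisible(dir)
}

#' @rdname writeCorpus
#' @param requireContacts error when a pair's contact TSV is missing
#'   (set `FALSE` for prediction-only corpora, where missing maps
#'   become empty).
#' @export
readCorpus <- function(dir, requireContacts = TRUE) {
  prot <- readProteinFasta(file.path(dir, "proteins.fasta"))
  rna <- readRnaFasta(file.path(dir, "rnas.fasta"))
  ss8 <- readAnnotations(file.path(dir, "ss8.tsv"))
  db <- readAnnotations(file.path(dir, "dotbracket.tsv"))
  ids <- names(prot)
  missing <- setdiff(ids, intersect(intersect(names(rna), names(ss8)), names(db)))
  if (length(missing) > 0L)
    .dataError(paste("ids missing from one of the corpus files:",
                     paste(missing, collapse = ", ")))
  lapply(ids, function(id) {
    p <- proteinRecord(id, prot[[id]], ss8[[id]])
    r <- rnaRecord(id, rna[[id]], db[[id]])
    cpath <- file.path(dir, "contacts", paste0(id, ".tsv"))
    map <- if (file.exists(cpath))
      readContactMap(cpath, nchar(prot[[id]]), nchar(rna[[id]]))
    else if (requireContacts)
      .dataError(paste("missing contact map for id", id))
    else contactMap(nResidues = nchar(prot[[id]]), nBases = nchar(rna[[id]]))
    trainingInstance(p, r, map)
  })
}
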