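## Central S4 classes.  All indices are 1-based at every user-facing
## surface; file formats are converted at the I/O boundary.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
RNA_ALPHABET <- c("A", "C", "G", "U")
SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "-")
PROFILE_ALPHABET <- c("E", "H", "I", "B", "M", "S")

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.checkAlphabet <- function(s, alphabet, what) {
  ch <- .chars(s)
  bad <- which(!(ch %in% alphabet))
  if (length(bad) > 0L) {
    return(sprintf("illegal character '%s' in %s at position %d",
                   ch[bad[1L]], what, bad[1L]))
  }
  NULL
}

#' ProteinRecord: a protein sequence with its 8-state secondary structure
#'
#' Holds one protein chain: an identifier, the amino-acid sequence over
#' the 20 canonical letters, and an equal-length 8-state secondary
#' structure string (alpha-helix H, 3-helix G, 5-helix I, strand E,
#' beta-turn B, turn T, bend S, coil -) as produced by an SSpro8-class
#' predictor.
#'
#' @slot id character(1) record identifier.
#' @slot sequence character(1) amino-acid sequence.
#' @slot ss8 character(1) 8-state secondary structure string.
#' @exportClass ProteinRecord
setClass("ProteinRecord",
         representation(id = "character", sequence = "character",
                        ss8 = "character"))

setValidity("ProteinRecord", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L || is.na(object@id))
    msgs <- c(msgs, "id must be a single string")
  if (nchar(object@sequence) != nchar(object@ss8))
    msgs <- c(msgs, "sequence and ss8 must have equal length")
  m <- .checkAlphabet(object@sequence, AA_ALPHABET,
                      sprintf("protein sequence '%s'", object@id))
  if (!is.null(m)) msgs <- c(msgs, m)
  m <- .checkAlphabet(object@ss8, SS8_ALPHABET,
                      sprintf("ss8 string '%s'", object@id))
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinRecord
#'
#' @param id record identifier.
#' @param sequence amino-acid sequence (20 canonical letters).
#' @param ss8 8-state secondary structure string of equal length.
#' @return A [ProteinRecord-class] object.
#' @examples
#' proteinRecord("p1", "MKV", "HHH")
#' @export
proteinRecord <- function(id, sequence, ss8) {
  new("ProteinRecord", id = as.character(id),
      sequence = toupper(sequence), ss8 = ss8)
}

#' RNARecord: an RNA sequence with dot-bracket structure and loop profile
#'
#' Holds one RNA chain: identifier, sequence over ACGU, a balanced
#' non-crossing dot-bracket string (as produced by a CentroidFold-class
#' predictor), and the derived per-base 6-state structural profile
#' (external loop E, hairpin loop H, internal loop I, bulge B,
#' multibranch loop M, stack S).  The profile is computed from the
#' dot-bracket by [rnaProfile()] and satisfies `profile[j] == "S"` iff
#' base j is paired.
#'
#' @slot id character(1) record identifier.
#' @slot sequence character(1) RNA sequence.
#' @slot dotbracket character(1) dot-bracket string.
#' @slot profile character(1) 6-state structural profile.
#' @exportClass RNARecord
setClass("RNARecord",
         representation(id = "character", sequence = "character",
                        dotbracket = "character", profile = "character"))

setValidity("RNARecord", function(object) {
  msgs <- character(0)
  n <- nchar(object@sequence)
  if (nchar(object@dotbracket) != n || nchar(object@profile) != n)
    msgs <- c(msgs, "sequence, dotbracket and profile must have equal length")
  m <- .checkAlphabet(object@sequence, RNA_ALPHABET,
                      sprintf("RNA sequence '%s'", object@id))
  if (!is.null(m)) msgs <- c(msgs, m)
  m <- .checkAlphabet(object@profile, PROFILE_ALPHABET,
                      sprintf("profile '%s'", object@id))
  if (!is.null(m)) msgs <- c(msgs, m)
  if (length(msgs) == 0L) {
    pairs <- tryCatch(parseDotBracket(object@dotbracket),
                      error = function(e) e)
    if (inherits(pairs, "error")) {
      msgs <- c(msgs, conditionMessage(pairs))
    } else {
      paired <- logical(n)
      paired[c(pairs[, 1L], pairs[, 2L])] <- TRUE
      prof <- .chars(object@profile)
      if (!all((prof == "S") == paired))
        msgs <- c(msgs, "profile must be 'S' exactly at paired positions")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an RNARecord
#'
#' The 6-state structural profile is derived from the dot-bracket string.
#'
#' @param id record identifier.
#' @param sequence RNA sequence over ACGU (T is mapped to U).
#' @param dotbracket balanced dot-bracket string of equal length.
#' @return An [RNARecord-class] object.
#' @examples
#' rnaRecord("r1", "GGGAAACCC", "(((...)))")
#' @export
rnaRecord <- function(id, sequence, dotbracket) {
  sequence <- chartr("T", "U", toupper(sequence))
  new("RNARecord", id = as.character(id), sequence = sequence,
      dotbracket = dotbracket, profile = rnaProfile(dotbracket))
}

#' ContactMap: a binary residue-base contact matrix in sparse form
#'
#' Represents the |P| x |R| binary contact matrix z of a protein-RNA
#' pair as a set of 1-based (residue, base) index pairs.  The
#' binding-site indicators x_i (residue i has at least one contact) and
#' y_j (base j has at least one contact) are derived views, available
#' through [bindingIndicators()].
#'
#' @slot nResidues integer(1) number of residues |P|.
#' @slot nBases integer(1) number of bases |R|.
#' @slot contacts integer matrix with two columns (residue index, base
#'   index), rows unique and ordered.
#' @exportClass ContactMap
setClass("ContactMap",
         representation(nResidues = "integer", nBases = "integer",
                        contacts = "matrix"))

setValidity("ContactMap", function(object) {
  msgs <- character(0)
  if (object@nResidues < 1L || object@nBases < 1L)
    msgs <- c(msgs, "dimensions must be positive")
  cm <- object@contacts
  if (!is.integer(cm) || ncol(cm) != 2L)
    msgs <- c(msgs, "contacts must be an integer matrix with 2 columns")
  else if (nrow(cm) > 0L) {
    if (any(cm[, 1L] < 1L) || any(cm[, 1L] > object@nResidues) ||
        any(cm[, 2L] < 1L) || any(cm[, 2L] > object@nBases))
      msgs <- c(msgs, "contact indices out of bounds")
    if (anyDuplicated(cm))
      msgs <- c(msgs, "duplicate contacts")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ContactMap
#'
#' Duplicate pairs are collapsed and rows are sorted by residue then
#' base index.
#'
#' @param contacts two-column matrix (or data.frame) of 1-based
#'   (residue, base) index pairs; may have zero rows.
#' @param nResidues,nBases dimensions of the underlying binary matrix.
#' @return A [ContactMap-class] object.
#' @examples
#' contactMap(cbind(1, 2), nResidues = 2, nBases = 3)
#' @export
contactMap <- function(contacts = matrix(integer(0), ncol = 2),
                       nResidues, nBases) {
  cm <- as.matrix(contacts)
  if (length(cm) == 0L) cm <- matrix(integer(0), ncol = 2L)
  storage.mode(cm) <- "integer"
  dimnames(cm) <- NULL
  cm <- unique(cm)
  if (nrow(cm) > 1L) cm <- cm[order(cm[, 1L], cm[, 2L]), , drop = FALSE]
  new("ContactMap", nResidues = as.integer(nResidues),
      nBases = as.integer(nBases), contacts = cm)
}

#' ModelWeights: sparse feature-indexed weights of the scoring model
#'
#' A sparse mapping from feature keys to real weights; a key that is
#' absent has weight zero, and no stored key maps to an exact zero.
#' Feature keys are strings of the form `type<TAB>context` for unary
#' (residue or base) features and `type<TAB>contextA<TAB>contextB` for
#' residue-base contact features.
#'
#' @slot w named numeric vector of nonzero weights.
#' @exportClass ModelWeights
setClass("ModelWeights", representation(w = "numeric"))

setValidity("ModelWeights", function(object) {
  msgs <- character(0)
  w <- object@w
  if (length(w) > 0L) {
    if (is.null(names(w)) || anyNA(names(w)) || any(names(w) == ""))
      msgs <- c(msgs, "all weights must be named")
    if (anyDuplicated(names(w)))
      msgs <- c(msgs, "duplicate feature keys")
    if (any(!is.finite(w)))
      msgs <- c(msgs, "weights must be finite")
    if (any(w == 0))
      msgs <- c(msgs, "stored weights must be nonzero (prune exact zeros)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModelWeights object
#'
#' Exact-zero entries are pruned so that the sparse representation is
#' canonical.
#'
#' @param w named numeric vector (feature key -> weight); may be empty.
#' @return A [ModelWeights-class] object.
#' @export
modelWeights <- function(w = numeric(0)) {
  w <- w[w != 0]
  if (length(w) == 0L) w <- stats::setNames(numeric(0), character(0))
  new("ModelWeights", w = w)
}

#' ScoreTerms: precomputed per-variable scores of the IP objective
#'
#' The scoring function, linear in the features, can be rewritten as
#' sum_i u_i x_i + sum_j v_j y_j + sum_ij w_ij z_ij, where u, v and w
#' are the binding preferences of residues, bases and residue-base
#' pairs under the current weights.  `offset` is zero in plain decoding
#' and carries the constant part of the loss in loss-augmented decoding,
#' so that the augmented objective of any candidate map equals its
#' plain score plus its loss against the reference map.
#'
#' @slot u numeric vector, per-residue scores (length |P|).
#' @slot v numeric vector, per-base scores (length |R|).
#' @slot w numeric |P| x |R| matrix, per-pair scores.
#' @slot offset numeric(1) constant added to the objective.
#' @exportClass ScoreTerms
setClass("ScoreTerms",
         representation(u = "numeric", v = "numeric", w = "matrix",
                        offset = "numeric"))

setValidity("ScoreTerms", function(object) {
  msgs <- character(0)
  if (nrow(object@w) != length(object@u) ||
      ncol(object@w) != length(object@v))
    msgs <- c(msgs, "w must be |P| x |R| with |P| = length(u), |R| = length(v)")
  if (any(!is.finite(object@u)) || any(!is.finite(object@v)) ||
      any(!is.finite(object@w)) || !is.finite(object@offset))
    msgs <- c(msgs, "scores must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScoreTerms object
#'
#' @param u per-residue scores.
#' @param v per-base scores.
#' @param w per-pair score matrix (length(u) x length(v)).
#' @param offset constant objective offset (default 0).
#' @return A [ScoreTerms-class] object.
#' @export
scoreTerms <- function(u, v, w, offset = 0) {
  new("ScoreTerms", u = as.numeric(u), v = as.numeric(v),
      w = matrix(as.numeric(w), nrow = length(u)), offset = as.numeric(offset))
}

#' TrainingInstance: one labeled protein-RNA pair
#'
#' @slot protein a [ProteinRecord-class].
#' @slot rna an [RNARecord-class].
#' @slot map the true [ContactMap-class] for the pair.
#' @exportClass TrainingInstance
setClass("TrainingInstance",
         representation(protein = "ProteinRecord", rna = "RNARecord",
                        map = "ContactMap"))

setValidity("TrainingInstance", function(object) {
  if (object@map@nResidues != nchar(object@protein@sequence) ||
      object@map@nBases != nchar(object@rna@sequence))
    return("contact map dimensions do not match the sequences")
  TRUE
})

#' Construct a TrainingInstance
#'
#' @param protein a [ProteinRecord-class].
#' @param rna an [RNARecord-class].
#' @param map the true [ContactMap-class]; dimensions must match.
#' @return A [TrainingInstance-class] object.
#' @export
trainingInstance <- function(protein, rna, map) {
  new("TrainingInstance", protein = protein, rna = rna, map = map)
}

#' Hyperparameters of loss, regularization, optimization and decoding
#'
#' Defaults follow the published calibration: false-negative penalties
#' 0.5 and false-positive penalties 0.005 at all three levels (residue,
#' base, contact), l1 weight C = 1e-5, and contact caps Xi = Yj = 8.
#' The optimizer constants (base learning rate eta = 1, AdaGrad epsilon
#' = 1e-8, convergence tolerance 1e-6, at most 100 epochs) are package
#' defaults.
#'
#' @slot deltaFnResidue,deltaFpResidue,deltaFnBase,deltaFpBase,deltaFnContact,deltaFpContact
#'   nonnegative loss penalties.
#' @slot C nonnegative l1 regularization weight.
#' @slot eta positive base learning rate.
#' @slot epsilon AdaGrad stabilizer.
#' @slot tol convergence tolerance on the max per-epoch weight change.
#' @slot maxEpochs positive integer epoch cap.
#' @slot Xcap,Ycap per-residue / per-base contact caps (may be `Inf`).
#' @exportClass Hyperparameters
setClass("Hyperparameters",
         representation(deltaFnResidue = "numeric", deltaFpResidue = "numeric",
                        deltaFnBase = "numeric", deltaFpBase = "numeric",
                        deltaFnContact = "numeric", deltaFpContact = "numeric",
                        C = "numeric", eta = "numeric", epsilon = "numeric",
                        tol = "numeric", maxEpochs = "integer",
                        Xcap = "numeric", Ycap = "numeric"),
         prototype(C = 1e-5))

setValidity("Hyperparameters", function(object) {
  msgs <- character(0)
  deltas <- c(object@deltaFnResidue, object@deltaFpResidue,
              object@deltaFnBase, object@deltaFpBase,
              object@deltaFnContact, object@deltaFpContact)
  if (any(deltas < 0)) msgs <- c(msgs, "loss penalties must be nonnegative")
  if (object@C < 0) msgs <- c(msgs, "C must be nonnegative")
  if (object@eta <= 0) msgs <- c(msgs, "eta must be positive")
  if (object@maxEpochs < 1L) msgs <- c(msgs, "maxEpochs must be positive")
  if (object@Xcap < 1 || object@Ycap < 1)
    msgs <- c(msgs, "caps must be >= 1 (use Inf for unbounded)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Hyperparameters object
#'
#' @param deltaFnResidue,deltaFpResidue,deltaFnBase,deltaFpBase,deltaFnContact,deltaFpContact
#'   loss penalties for false negatives / false positives at the
#'   residue, base and contact level.
#' @param C l1 regularization weight.
#' @param eta base learning rate for AdaGrad.
#' @param epsilon AdaGrad denominator stabilizer.
#' @param tol convergence tolerance (max absolute weight change per epoch).
#' @param maxEpochs maximum number of training epochs.
#' @param Xcap,Ycap contact caps per residue and per base (`Inf` =
#'   unbounded).
#' @return A [Hyperparameters-class] object.
#' @examples
#' hyperParams()                   # published defaults
#' hyperParams(Xcap = 1, Ycap = 1) # strictest decoding
#' @export
hyperParams <- function(deltaFnResidue = 0.5, deltaFpResidue = 0.005,
                        deltaFnBase = 0.5, deltaFpBase = 0.005,
                        deltaFnContact = 0.5, deltaFpContact = 0.005,
                        C = 1e-5, eta = 1, epsilon = 1e-8, tol = 1e-6,
                        maxEpochs = 100L, Xcap = 8, Ycap = 8) {
  ## the slot named C would partially match new()'s Class argument, so
  ## slots are assigned explicitly
  obj <- new("Hyperparameters",
             deltaFnResidue = deltaFnResidue, deltaFpResidue = deltaFpResidue,
             deltaFnBase = deltaFnBase, deltaFpBase = deltaFpBase,
             deltaFnContact = deltaFnContact, deltaFpContact = deltaFpContact,
             eta = eta, epsilon = epsilon, tol = tol,
             maxEpochs = as.integer(maxEpochs), Xcap = Xcap, Ycap = Ycap)
  obj@C <- C
  validObject(obj)
  obj
}

#' SyntheticConfig: parameters of the synthetic corpus generator
#'
#' @slot nPairs number of protein-RNA pairs to generate.
#' @slot proteinLengthRange,rnaLengthRange inclusive integer ranges.
#' @slot plantedSparsity fraction of realizable feature keys given a
#'   nonzero planted weight.
#' @slot plantedScale standard deviation of planted weights.
#' @slot seed integer seed; the corpus is deterministic given it.
#' @slot Xcap,Ycap contact caps used when labeling by inference.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
         representation(nPairs = "integer", proteinLengthRange = "integer",
                        rnaLengthRange = "integer", plantedSparsity = "numeric",
                        plantedScale = "numeric", seed = "integer",
                        Xcap = "numeric", Ycap = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character(0)
  if (object@nPairs < 1L) msgs <- c(msgs, "nPairs must be >= 1")
  if (length(object@proteinLengthRange) != 2L ||
      length(object@rnaLengthRange) != 2L)
    msgs <- c(msgs, "length ranges must have two elements")
  else {
    if (object@proteinLengthRange[1L] < 3L || object@rnaLengthRange[1L] < 3L)
      msgs <- c(msgs, "minimum lengths must be >= 3")
    if (diff(object@proteinLengthRange) < 0 || diff(object@rnaLengthRange) < 0)
      msgs <- c(msgs, "length ranges must be nondecreasing")
  }
  if (object@plantedSparsity <= 0 || object@plantedSparsity > 1)
    msgs <- c(msgs, "plantedSparsity must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SyntheticConfig
#'
#' Defaults: 10 pairs, protein lengths 10-20, RNA lengths 10-28 (the RNA
#' upper end leaves room for multibranch loops -- the smallest one needs
#' 24 nt -- so all six profile states occur with positive probability
#' across a corpus), planted sparsity 0.02, planted scale 1, caps 8.
#'
#' @param nPairs number of pairs.
#' @param proteinLengthRange,rnaLengthRange inclusive length ranges.
#' @param plantedSparsity fraction of realizable keys planted nonzero.
#' @param plantedScale standard deviation of planted weights.
#' @param seed integer seed.
#' @param Xcap,Ycap contact caps used when labeling.
#' @return A [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nPairs = 10L, proteinLengthRange = c(10L, 20L),
                            rnaLengthRange = c(10L, 28L),
                            plantedSparsity = 0.02, plantedScale = 1,
                            seed = 1L, Xcap = 8, Ycap = 8) {
  new("SyntheticConfig", nPairs = as.integer(nPairs),
      proteinLengthRange = as.integer(proteinLengthRange),
      rnaLengthRange = as.integer(rnaLengthRange),
      plantedSparsity = plantedSparsity, plantedScale = plantedScale,
      seed = as.integer(seed), Xcap = Xcap, Ycap = Ycap)
}
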