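## Sparse feature extraction.
##
## The model scores a candidate contact map through three families of
## binary local features, each counted once per firing site:
##   - residue features at every binding residue (x_i = 1): k-mers of
##     the amino-acid sequence (k = 3, 5), of the 10-group and 4-group
##     simplified alphabets (k = 5, 7), and of the 8-state secondary
##     structure (k = 3, 5);
##   - base features at every binding base (y_j = 1): k-mers of the
##     RNA sequence and of the 6-state structural profile (k = 3, 5);
##   - contact features at every contact (i, j): pairs of equal-length
##     windows, one on the protein side and one on the RNA side, for
##     six track combinations at k = 3 and k = 5.
## Windows at the sequence boundary are padded with a sentinel so that
## every position yields a full-length window.

G10_MAP <- c(L = "L", V = "L", I = "L", M = "L", C = "C", A = "A",
             G = "G", S = "S", T = "S", P = "P", F = "F", Y = "F",
             W = "F", E = "E", D = "E", N = "E", Q = "E", K = "K",
             R = "K", H = "H")
G4_MAP <- c(L = "L", V = "L", I = "L", M = "L", C = "L", A = "A",
            G = "A", S = "A", T = "A", P = "A", F = "F", Y = "F",
            W = "F", E = "E", D = "E", N = "E", Q = "E", K = "E",
            R = "E", H = "E")

#' FeatureConfig: the feature families and window sizes of the model
#'
#' Describes every feature row: unary residue rows (track, window size),
#' unary base rows, and contact rows (protein track x RNA track, one
#' window size each side).  Window sizes are odd (windows are centered);
#' boundary positions are padded with `pad`.
#'
#' @slot residueRows data.frame(type, source, k) for residue features.
#' @slot baseRows data.frame(type, source, k) for base features.
#' @slot contactRows data.frame(type, psource, rsource, k) for contact
#'   features.
#' @slot pad single padding character for out-of-range window positions.
#' @exportClass FeatureConfig
setClass("FeatureConfig",
         representation(residueRows = "data.frame", baseRows = "data.frame",
                        contactRows = "data.frame", pad = "character"))

setValidity("FeatureConfig", function(object) {
  ks <- c(object@residueRows$k, object@baseRows$k, object@contactRows$k)
  if (any(ks %% 2L == 0L)) return("all window sizes must be odd")
  if (nchar(object@pad) != 1L) return("pad must be a single character")
  TRUE
})

#' Construct the default FeatureConfig
#'
#' The default matches the published feature tables: residue k-mers at
#' k = 3, 5; simplified-alphabet k-mers at k = 5, 7; protein secondary
#' structure k-mers at k = 3, 5; base and RNA-profile k-mers at k = 3,
#' 5; and twelve contact rows (residue x base, protSS x rnaSS,
#' sa10 x base, sa10 x rnaSS, sa4 x base, sa4 x rnaSS, each at k = 3
#' and k = 5).  Note the simplified alphabets use k in {5, 7} as unary
#' features but k in {3, 5} inside contact features, as published.
#'
#' @param pad sentinel character for boundary windows (default `^`).
#' @return A [FeatureConfig-class].
#' @export
featureConfig <- function(pad = "^") {
  residueRows <- data.frame(
    type = c("residue-3mer", "residue-5mer", "sa10-5mer", "sa10-7mer",
             "sa4-5mer", "sa4-7mer", "protss-3mer", "protss-5mer"),
    source = c("seq", "seq", "g10", "g10", "g4", "g4", "ss8", "ss8"),
    k = c(3L, 5L, 5L, 7L, 5L, 7L, 3L, 5L),
    stringsAsFactors = FALSE)
  baseRows <- data.frame(
    type = c("base-3mer", "base-5mer", "rnass-3mer", "rnass-5mer"),
    source = c("seq", "seq", "profile", "profile"),
    k = c(3L, 5L, 3L, 5L),
    stringsAsFactors = FALSE)
  combos <- data.frame(
    tag = c("res", "protss", "sa10", "sa10", "sa4", "sa4"),
    psource = c("seq", "ss8", "g10", "g10", "g4", "g4"),
    rtag = c("base", "rnass", "base", "rnass", "base", "rnass"),
    rsource = c("seq", "profile", "seq", "profile", "seq", "profile"),
    stringsAsFactors = FALSE)
  contactRows <- do.call(rbind, lapply(c(3L, 5L), function(k) {
    data.frame(type = sprintf("contact:%s%dx%s%d", combos$tag, k,
                              combos$rtag, k),
               psource = combos$psource, rsource = combos$rsource, k = k,
               stringsAsFactors = FALSE)
  }))
  new("FeatureConfig", residueRows = residueRows, baseRows = baseRows,
      contactRows = contactRows, pad = pad)
}

#' Extract a centered, padded k-mer window
#'
#' Positions outside `[1, nchar(s)]` are filled with the pad character,
#' so every center yields a window of exactly `k` characters.
#'
#' @param s string.
#' @param center 1-based center position(s); vectorized.
#' @param k odd window size.
#' @param pad single padding character.
#' @return character vector of windows, one per center.
#' @examples
#' kmerWindow("MKV", 2, 3)  # "MKV"
#' kmerWindow("MKV", 1, 3)  # "^MK"
#' @export
kmerWindow <- function(s, center, k, pad = "^") {
  if (k %% 2L == 0L) stop("window size k must be odd, got ", k)
  stopifnot(all(center >= 1L), all(center <= nchar(s)))
  h <- (k - 1L) %/% 2L
  padded <- paste0(strrep(pad, h), s, strrep(pad, h))
  substring(padded, center, center + k - 1L)
}

#' Map an amino-acid string onto a simplified alphabet
#'
#' The 20 canonical letters are grouped (10 groups: LVIM, C, A, G, ST,
#' P, FYW, EDNQ, KR, H; 4 groups: LVIMC, AGSTP, FYW, EDNQKRH) and each
#' letter is replaced by its group's representative, the first letter of
#' the printed group.
#'
#' @param s amino-acid string.
#' @param scheme `"g10"` or `"g4"`.
#' @return string over the group representatives.
#' @examples
#' simplifyAlphabet("LVC", "g10")  # "LLC"
#' simplifyAlphabet("LVC", "g4")   # "LLL"
#' @export
simplifyAlphabet <- function(s, scheme = c("g10", "g4")) {
  scheme <- match.arg(scheme)
  if (nchar(s) == 0L) return(s)
  m <- .checkAlphabet(s, AA_ALPHABET, "amino-acid string")
  if (!is.null(m)) stop("alphabet validation error: ", m)
  map <- if (scheme == "g10") G10_MAP else G4_MAP
  chartr(paste(names(map), collapse = ""), paste(map, collapse = ""), s)
}

## character tracks a feature row can draw windows from
.proteinTracks <- function(P) {
  list(seq = P@sequence,
       g10 = simplifyAlphabet(P@sequence, "g10"),
       g4 = simplifyAlphabet(P@sequence, "g4"),
       ss8 = P@ss8)
}

.rnaTracks <- function(R) list(seq = R@sequence, profile = R@profile)

.countKeys <- function(keys) {
  if (length(keys) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(keys)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Residue, base, contact and full feature vectors
#'
#' `residueFeatures` counts, for every binding residue (x_i = 1), one
#' occurrence of each configured residue feature row's window at i;
#' `baseFeatures` does the same over binding bases; `contactFeatures`
#' counts, for every contact (i, j), one occurrence of each contact
#' row's window pair; `fullFeatures` concatenates the three families
#' (their key spaces are disjoint) using the indicators derived from
#' the map.
#'
#' @param P a [ProteinRecord-class].
#' @param R an [RNARecord-class].
#' @param x,y binary indicator vectors (length |P| / |R|).
#' @param z,map a [ContactMap-class].
#' @param config a [FeatureConfig-class].
#' @return named numeric vector of feature counts (sparse; empty if no
#'   site fires).
#' @export
residueFeatures <- function(P, x, config = featureConfig()) {
  stopifnot(length(x) == nchar(P@sequence))
  pos <- which(x == 1L)
  if (length(pos) == 0L) return(.countKeys(character(0)))
  tracks <- .proteinTracks(P)
  rows <- config@residueRows
  keys <- unlist(lapply(seq_len(nrow(rows)), function(r) {
    paste0(rows$type[r], "\t",
           kmerWindow(tracks[[rows$source[r]]], pos, rows$k[r], config@pad))
  }), use.names = FALSE)
  .countKeys(keys)
}

#' @rdname residueFeatures
#' @export
baseFeatures <- function(R, y, config = featureConfig()) {
  stopifnot(length(y) == nchar(R@sequence))
  pos <- which(y == 1L)
  if (length(pos) == 0L) return(.countKeys(character(0)))
  tracks <- .rnaTracks(R)
  rows <- config@baseRows
  keys <- unlist(lapply(seq_len(nrow(rows)), function(r) {
    paste0(rows$type[r], "\t",
           kmerWindow(tracks[[rows$source[r]]], pos, rows$k[r], config@pad))
  }), use.names = FALSE)
  .countKeys(keys)
}

#' @rdname residueFeatures
#' @export
contactFeatures <- function(P, R, z, config = featureConfig()) {
  cm <- contacts(z)
  stopifnot(nResidues(z) == nchar(P@sequence),
            nBases(z) == nchar(R@sequence))
  if (nrow(cm) == 0L) return(.countKeys(character(0)))
  ptracks <- .proteinTracks(P)
  rtracks <- .rnaTracks(R)
  rows <- config@contactRows
  keys <- unlist(lapply(seq_len(nrow(rows)), function(r) {
    paste0(rows$type[r], "\t",
           kmerWindow(ptracks[[rows$psource[r]]], cm[, 1L], rows$k[r], config@pad),
           "\t",
           kmerWindow(rtracks[[rows$rsource[r]]], cm[, 2L], rows$k[r], config@pad))
  }), use.names = FALSE)
  .countKeys(keys)
}

#' @rdname residueFeatures
#' @export
fullFeatures <- function(P, R, z, config = featureConfig()) {
  ind <- bindingIndicators(z)
  c(residueFeatures(P, ind$x, config),
    baseFeatures(R, ind$y, config),
    contactFeatures(P, R, z, config))
}

.lookupWeights <- function(model, keys) {
  w <- featureWeights(model)
  idx <- match(keys, names(w))
  out <- unname(w[idx])
  out[is.na(idx)] <- 0
  out
}

#' Score a contact map under a model
#'
#' The score is the inner product of the model weights with the full
#' feature vector of the map; keys absent from the model contribute 0.
#'
#' @inheritParams residueFeatures
#' @param model a [ModelWeights-class].
#' @return numeric(1) score.
#' @export
scoreContactMap <- function(P, R, z, model, config = featureConfig()) {
  phi <- fullFeatures(P, R, z, config)
  if (length(phi) == 0L) return(0)
  sum(.lookupWeights(model, names(phi)) * phi)
}

#' Precompute the per-variable scores u, v, w for IP decoding
#'
#' u_i sums the model weights of the residue-feature keys generated at
#' position i (as if x_i = 1); v_j and w_ij are the analogous sums for
#' base and contact keys.  For any contact map whose indicators x, y
#' are derived from z, the linear form
#' sum_i u_i x_i + sum_j v_j y_j + sum_ij w_ij z_ij equals
#' [scoreContactMap()] exactly.
#'
#' @inheritParams scoreContactMap
#' @return A [ScoreTerms-class] with offset 0.
#' @export
computeScoreTerms <- function(P, R, model, config = featureConfig()) {
  keys <- .scoreTermKeys(P, R, config)
  .termsFromKeys(keys, model)
}

## key strings for every position / cell; reused across many lookups in
## training, where only the weights change between iterations
.scoreTermKeys <- function(P, R, config = featureConfig()) {
  nP <- nchar(P@sequence)
  nR <- nchar(R@sequence)
  ptracks <- .proteinTracks(P)
  rtracks <- .rnaTracks(R)
  rr <- config@residueRows
  uKeys <- lapply(seq_len(nrow(rr)), function(r) {
    paste0(rr$type[r], "\t",
           kmerWindow(ptracks[[rr$source[r]]], seq_len(nP), rr$k[r], config@pad))
  })
  br <- config@baseRows
  vKeys <- lapply(seq_len(nrow(br)), function(r) {
    paste0(br$type[r], "\t",
           kmerWindow(rtracks[[br$source[r]]], seq_len(nR), br$k[r], config@pad))
  })
  cr <- config@contactRows
  wKeys <- lapply(seq_len(nrow(cr)), function(r) {
    wp <- kmerWindow(ptracks[[cr$psource[r]]], seq_len(nP), cr$k[r], config@pad)
    wr <- kmerWindow(rtracks[[cr$rsource[r]]], seq_len(nR), cr$k[r], config@pad)
    ## column-major |P| x |R| layout
    paste0(cr$type[r], "\t", rep(wp, times = nR), "\t", rep(wr, each = nP))
  })
  list(u = uKeys, v = vKeys, w = wKeys, nP = nP, nR = nR)
}

.termsFromKeys <- function(keys, model) {
  u <- numeric(keys$nP)
  for (kk in keys$u) u <- u + .lookupWeights(model, kk)
  v <- numeric(keys$nR)
  for (kk in keys$v) v <- v + .lookupWeights(model, kk)
  w <- matrix(0, keys$nP, keys$nR)
  for (kk in keys$w) w <- w + matrix(.lookupWeights(model, kk), keys$nP)
  scoreTerms(u, v, w, offset = 0)
}
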