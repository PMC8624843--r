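# Independent oracles used to verify the package implementations.

# Brute-force loop classifier: for each unpaired position, explicitly
# find the innermost enclosing pair by scanning all pairs, enumerate the
# loop's directly enclosed pairs, and apply the loop taxonomy.  Shares
# no code with rnaProfile().
bruteProfileClassifier <- function(s) {
  n <- nchar(s)
  if (n == 0L) return("")
  ch <- strsplit(s, "")[[1]]
  st <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      pairs <- rbind(pairs, c(st[length(st)], i))
      st <- st[-length(st)]
    }
  }
  out <- rep("", n)
  if (nrow(pairs) > 0L) out[as.vector(pairs)] <- "S"
  for (j in which(out == "")) {
    enc <- pairs[pairs[, 1] < j & pairs[, 2] > j, , drop = FALSE]
    if (nrow(enc) == 0L) { out[j] <- "E"; next }
    inner <- enc[which.max(enc[, 1]), ]
    p <- inner[1]; q <- inner[2]
    inside <- pairs[pairs[, 1] > p & pairs[, 2] < q, , drop = FALSE]
    if (nrow(inside) > 0L) {
      isChild <- vapply(seq_len(nrow(inside)), function(r) {
        !any(inside[, 1] < inside[r, 1] & inside[, 2] > inside[r, 2])
      }, logical(1))
      inside <- inside[isChild, , drop = FALSE]
    }
    k <- nrow(inside)
    out[j] <- if (k == 0L) "H"
      else if (k >= 2L) "M"
      else {
        gap5 <- inside[1, 1] - p - 1L
        gap3 <- q - inside[1, 2] - 1L
        if (gap5 > 0L && gap3 > 0L) "I" else "B"
      }
  }
  paste(out, collapse = "")
}

# Arbitrary balanced dot-bracket strings (stems of one pair, empty
# hairpins, deep nesting all possible) -- a wider family than the
# package's stem-loop sampler, for stress-testing the profile code.
randomBalancedDotBracket <- function(n) {
  if (n <= 0L) return("")
  if (n == 1L) return(".")
  if (stats::runif(1) < 0.4) {
    paste0(".", randomBalancedDotBracket(n - 1L))
  } else {
    a <- sample.int(n - 1L, 1L) - 1L        # 0 .. n-2 inside the pair
    paste0("(", randomBalancedDotBracket(a), ")",
           randomBalancedDotBracket(n - 2L - a))
  }
}

# direct evaluation of the linear objective of a map under score terms,
# written independently of the package internals
objectiveByHand <- function(terms, map) {
  ind <- bindingIndicators(map)
  cm <- contacts(map)
  val <- sum(terms@u * ind$x) + sum(terms@v * ind$y) + terms@offset
  if (nrow(cm) > 0L) {
    for (r in seq_len(nrow(cm))) val <- val + terms@w[cm[r, 1], cm[r, 2]]
  }
  val
}

# enumerate every binary map of given dimensions (feasible or not)
allMaps <- function(nP, nR) {
  ncell <- nP * nR
  lapply(seq_len(2^ncell) - 1L, function(id) {
    sel <- which(bitwAnd(id, 2^(seq_len(ncell) - 1L)) > 0L)
    contactMap(cbind((sel - 1L) %/% nR + 1L, (sel - 1L) %% nR + 1L), nP, nR)
  })
}

randomTerms <- function(nP, nR, lo = -2, hi = 2) {
  scoreTerms(stats::runif(nP, lo, hi), stats::runif(nR, lo, hi),
             matrix(stats::runif(nP * nR, lo, hi), nP))
}

randomConsistentMap <- function(nP, nR, p = 0.3) {
  sel <- which(stats::runif(nP * nR) < p)
  contactMap(cbind((sel - 1L) %% nP + 1L, (sel - 1L) %/% nP + 1L), nP, nR)
}

randomProteinRecord <- function(id, n) {
  proteinRecord(id,
                paste(sample(PRIcontact:::AA_ALPHABET, n, TRUE), collapse = ""),
                paste(sample(PRIcontact:::SS8_ALPHABET, n, TRUE), collapse = ""))
}

randomRnaRecord <- function(id, n) {
  rnaRecord(id,
            paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = ""),
            sampleDotBracket(n))
}
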