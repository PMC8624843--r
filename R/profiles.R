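## RNA secondary-structure profiles and protein structure validation.
##
## An RNA secondary structure in dot-bracket notation decomposes
## uniquely into loops.  Each base is assigned one of six structural
## elements: paired bases are stacks (S); an unpaired base takes the
## class of its innermost enclosing loop -- external (E) when no pair
## encloses it, hairpin (H) when the loop closes zero inner pairs,
## internal (I) or bulge (B) when it closes exactly one (both gaps
## around the inner pair occupied vs only one), and multibranch (M)
## when it closes two or more.

#' Parse a dot-bracket string into base pairs
#'
#' Pseudoknot-free Vienna-style strings over `(`, `)` and `.` only;
#' unbalanced input is rejected with the offending position.
#'
#' @param s dot-bracket string.
#' @return integer matrix with columns `open`, `close` (1-based, sorted
#'   by opening position); zero rows if unpaired everywhere.
#' @examples
#' parseDotBracket("(())")
#' @export
parseDotBracket <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  ch <- .chars(s)
  bad <- which(!(ch %in% c("(", ")", ".")))
  if (length(bad) > 0L)
    stop(sprintf("dot-bracket parse error: illegal character '%s' at position %d",
                 ch[bad[1L]], bad[1L]))
  stack <- integer(0)
  open <- integer(0)
  close <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        stop(sprintf("dot-bracket parse error: unmatched ')' at position %d", i))
      open <- c(open, stack[length(stack)])
      close <- c(close, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L)
    stop(sprintf("dot-bracket parse error: unmatched '(' at position %d",
                 stack[length(stack)]))
  pairs <- cbind(open = open, close = close)
  if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  pairs
}

#' Assign the 6-state structural profile to each base
#'
#' Converts a balanced dot-bracket string into a profile string over
#' `E` (external loop), `H` (hairpin loop), `I` (internal loop), `B`
#' (bulge), `M` (multibranch loop) and `S` (stack).  Paired positions
#' are always `S`.  An unpaired position is classified by the loop
#' closed by its innermost enclosing pair: zero inner pairs give `H`;
#' one inner pair gives `I` when both the 5' gap (between the closing
#' pair's opening base and the inner pair's opening base) and the 3'
#' gap are occupied, and `B` when exactly one is; two or more inner
#' pairs give `M`.  Positions outside every pair are `E`, including
#' unpaired stretches between separate stems.
#'
#' @param s dot-bracket string.
#' @return profile string of the same length.
#' @examples
#' rnaProfile("(((...)))")    # "SSSHHHSSS"
#' rnaProfile("((.((...))))") # "SSBSSHHHSSSS"
#' @export
rnaProfile <- function(s) {
  n <- nchar(s)
  if (n == 0L) return("")
  pairs <- parseDotBracket(s)
  ch <- .chars(s)
  out <- character(n)

  ## single left-to-right scan building the loop tree: for each '.' the
  ## enclosing open position; for each closed pair its parent pair
  encl <- integer(n)          # innermost enclosing open position, 0 = exterior
  parent <- integer(n)        # for an open position: open pos of parent pair
  children <- vector("list", n)  # open pos -> integer vector of child open pos
  extChildren <- integer(0)
  stack <- integer(0)
  for (i in seq_len(n)) {
    top <- if (length(stack)) stack[length(stack)] else 0L
    if (ch[i] == "(") {
      parent[i] <- top
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      op <- stack[length(stack)]
      stack <- stack[-length(stack)]
      up <- parent[op]
      if (up == 0L) extChildren <- c(extChildren, op)
      else children[[up]] <- c(children[[up]], op)
    } else {
      encl[i] <- top
    }
  }

  out[c(pairs[, 1L], pairs[, 2L])] <- "S"
  closeOf <- integer(n)
  closeOf[pairs[, 1L]] <- pairs[, 2L]

  unpaired <- which(out == "")
  for (i in unpaired) {
    op <- encl[i]
    if (op == 0L) { out[i] <- "E"; next }
    kids <- children[[op]]
    nk <- length(kids)
    if (nk == 0L) {
      out[i] <- "H"
    } else if (nk >= 2L) {
      out[i] <- "M"
    } else {
      gap5 <- kids[1L] - op - 1L
      gap3 <- closeOf[op] - closeOf[kids[1L]] - 1L
      out[i] <- if (gap5 > 0L && gap3 > 0L) "I" else "B"
    }
  }
  paste(out, collapse = "")
}

#' Validate an 8-state protein secondary structure string
#'
#' @param s candidate string over `H G I E B T S -`.
#' @return `s` unchanged if valid; otherwise an error naming the first
#'   offending position.
#' @examples
#' validateSs8("HHH-")
#' @export
validateSs8 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- .checkAlphabet(s, SS8_ALPHABET, "ss8 string")
  if (!is.null(m)) stop("ss8 validation error: ", m)
  s
}
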