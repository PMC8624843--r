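## Exact decoding of the maximum-scoring contact map.
##
## The decoder maximizes  sum_i u_i x_i + sum_j v_j y_j + sum_ij w_ij z_ij
## over binary z (with x, y the derived binding indicators) subject to
## the consistency constraints: contacts imply binding sites and vice
## versa, no bound base may be isolated (a bound base needs a bound
## inward neighbor; out-of-range neighbors count as unbound, so a
## length-1 RNA can never bind), and per-residue / per-base contact
## caps.  The default backend is an exact branch-and-cut 0/1 solver
## (HiGHS, driven through a bundled helper script); an exhaustive
## enumeration oracle is provided for small instances.

.pythonBin <- function() {
  bin <- getOption("PRIcontact.python", "")
  if (nzchar(bin)) return(bin)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found for the IP backend; set options(PRIcontact.python=)")
}

.solverScript <- function() {
  p <- system.file("python", "milp_solve.py", package = "PRIcontact")
  if (!nzchar(p)) stop("bundled solver script not found")
  p
}

.solverError <- function(msg) {
  stop(errorCondition(msg, class = c("priSolverError", "error", "condition")))
}

.dataError <- function(msg) {
  stop(errorCondition(msg, class = c("priDataError", "error", "condition")))
}

.capVector <- function(cap, n, what) {
  if (is.null(cap)) cap <- Inf
  cap <- as.numeric(cap)
  if (length(cap) == 1L) cap <- rep(cap, n)
  if (length(cap) != n) .dataError(sprintf("%s cap must be scalar or length %d", what, n))
  if (any(cap < 1)) .dataError(sprintf("%s caps must be >= 1 or Inf", what))
  cap
}

.objectiveOf <- function(terms, map) {
  ind <- bindingIndicators(map)
  cm <- contacts(map)
  sum(terms@u * ind$x) + sum(terms@v * ind$y) +
    (if (nrow(cm) > 0L) sum(terms@w[cm]) else 0) + terms@offset
}

#' Decode contact maps by exact integer programming (batch)
#'
#' Solves one IP per problem in a single call to the solver backend;
#' batching amortizes the backend start-up cost when many problems are
#' known in advance.
#'
#' @param problems list of problems, each a list with elements `terms`
#'   (a [ScoreTerms-class]), and optional `Xcap`, `Ycap` (scalar or
#'   per-position numeric; `Inf` = unbounded; default from `Xcap`/`Ycap`
#'   arguments).
#' @param Xcap,Ycap default caps applied to problems that do not carry
#'   their own.
#' @param solver `"highs"` (exact branch-and-cut; default, configurable
#'   via `options(PRIcontact.solver=)`) or `"bruteforce"` (exhaustive,
#'   only for |P| * |R| <= 20).
#' @return list of results, each a list with `map` (a
#'   [ContactMap-class], indicators re-derived from z) and `objective`
#'   (including any offset in the terms).
#' @export
predictContactsBatch <- function(problems, Xcap = 8, Ycap = 8,
                                 solver = getOption("PRIcontact.solver", "highs")) {
  solver <- match.arg(solver, c("highs", "bruteforce"))
  norm <- lapply(problems, function(p) {
    terms <- p$terms
    stopifnot(is(terms, "ScoreTerms"))
    list(terms = terms,
         Xcap = .capVector(if (is.null(p$Xcap)) Xcap else p$Xcap,
                           length(terms@u), "residue"),
         Ycap = .capVector(if (is.null(p$Ycap)) Ycap else p$Ycap,
                           length(terms@v), "base"))
  })
  if (solver == "bruteforce") {
    return(lapply(norm, function(p)
      predictBruteForce(p$terms, Xcap = p$Xcap, Ycap = p$Ycap)))
  }
  payload <- list(problems = lapply(norm, function(p) {
    nR <- length(p$terms@v)
    nP <- length(p$terms@u)
    ## a residue can have at most |R| contacts (and vice versa), so caps
    ## are finite on the wire even when logically unbounded
    list(u = p$terms@u, v = p$terms@v,
         w = as.vector(t(p$terms@w)),            # row-major for the helper
         xcap = pmin(p$Xcap, nR), ycap = pmin(p$Ycap, nP))
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = FALSE,
                       null = "null")
  status <- suppressWarnings(
    system2(.pythonBin(), c(.solverScript(), fin, fout),
            stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    .solverError(paste0("IP solver backend failed:\n",
                        paste(status, collapse = "\n")))
  res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)$results
  mapply(function(r, p) {
    if (r$status != 0)
      .solverError(sprintf("IP solver returned status %d: %s", r$status,
                           if (is.null(r$message)) "" else r$message))
    cm <- if (length(r$contacts) == 0L) matrix(integer(0), ncol = 2L)
          else do.call(rbind, lapply(r$contacts, unlist))
    map <- contactMap(cm, length(p$terms@u), length(p$terms@v))
    list(map = map, objective = .objectiveOf(p$terms, map))
  }, res, norm, SIMPLIFY = FALSE)
}

#' Decode the maximum-scoring contact map for one problem
#'
#' @param terms a [ScoreTerms-class] (see [computeScoreTerms()] and
#'   [lossAugment()]).
#' @inheritParams predictContactsBatch
#' @return list with `map` (a [ContactMap-class]) and `objective`.
#' @export
predictContacts <- function(terms, Xcap = 8, Ycap = 8,
                            solver = getOption("PRIcontact.solver", "highs")) {
  predictContactsBatch(list(list(terms = terms)), Xcap = Xcap, Ycap = Ycap,
                       solver = solver)[[1L]]
}

#' Exhaustive-enumeration decoding oracle
#'
#' Enumerates all 2^(|P| |R|) binary matrices, keeps those satisfying
#' the isolated-base and cap constraints (the indicator-consistency
#' constraints hold by derivation), and returns the maximizer.  Ties in
#' the objective are broken by the lexicographically smallest contact
#' set.  Intended as an independent verification oracle for small
#' instances only.
#'
#' @inheritParams predictContacts
#' @return list with `map` and `objective`.
#' @export
predictBruteForce <- function(terms, Xcap = Inf, Ycap = Inf) {
  stopifnot(is(terms, "ScoreTerms"))
  nP <- length(terms@u)
  nR <- length(terms@v)
  ncell <- nP * nR
  if (ncell > 20L)
    stop("instance too large for brute force: |P| * |R| = ", ncell, " > 20")
  Xcap <- .capVector(Xcap, nP, "residue")
  Ycap <- .capVector(Ycap, nR, "base")
  wvec <- as.vector(terms@w)                # cell b = (j - 1) * nP + i
  cellRow <- rep(seq_len(nP), times = nR)
  cellCol <- rep(seq_len(nR), each = nP)

  bestObj <- -Inf
  bestKey <- NULL
  bestContacts <- NULL
  total <- 2^ncell
  chunk <- 65536L
  startIds <- seq(0, total - 1, by = chunk)
  for (s in startIds) {
    ids <- s + seq_len(min(chunk, total - s)) - 1
    nb <- length(ids)
    bits <- matrix(0L, nb, ncell)
    for (b in seq_len(ncell))
      bits[, b] <- as.integer((ids %/% 2^(b - 1)) %% 2 == 1)
    rowCount <- matrix(0L, nb, nP)
    for (b in seq_len(ncell))
      rowCount[, cellRow[b]] <- rowCount[, cellRow[b]] + bits[, b]
    colCount <- matrix(0L, nb, nR)
    for (b in seq_len(ncell))
      colCount[, cellCol[b]] <- colCount[, cellCol[b]] + bits[, b]
    x <- rowCount > 0L
    y <- colCount > 0L
    ok <- rowSums(sweep(rowCount, 2L, Xcap, ">")) == 0 &
          rowSums(sweep(colCount, 2L, Ycap, ">")) == 0
    ## no isolated bound base: y_j = 1 needs a bound neighbor
    for (j in seq_len(nR)) {
      left <- if (j > 1L) y[, j - 1L] else FALSE
      right <- if (j < nR) y[, j + 1L] else FALSE
      ok <- ok & (!y[, j] | left | right)
    }
    if (!any(ok)) next
    obj <- as.vector(bits %*% wvec) + as.vector(x %*% terms@u) +
           as.vector(y %*% terms@v)
    obj[!ok] <- -Inf
    mx <- max(obj)
    if (mx < bestObj - 1e-9) next
    tied <- which(obj >= mx - 1e-9 & obj >= bestObj - 1e-9)
    for (t in tied) {
      sel <- which(bits[t, ] == 1L)
      cmat <- cbind(cellRow[sel], cellCol[sel])
      if (length(sel) > 1L)
        cmat <- cmat[order(cmat[, 1L], cmat[, 2L]), , drop = FALSE]
      key <- paste(sprintf("%04d%04d", cmat[, 1L], cmat[, 2L]), collapse = ";")
      if (obj[t] > bestObj + 1e-9 ||
          (obj[t] >= bestObj - 1e-9 && (is.null(bestKey) || key < bestKey))) {
        if (obj[t] > bestObj) bestObj <- obj[t]
        bestKey <- key
        bestContacts <- cmat
      }
    }
  }
  map <- contactMap(bestContacts, nP, nR)
  list(map = map, objective = .objectiveOf(terms, map))
}

#' Structured loss between two contact maps
#'
#' Counts disagreements at three levels -- binding residues, binding
#' bases (both via derived indicators) and contacts -- and weights
#' false negatives and false positives by the hyperparameter penalties:
#' delta_FN * #FN + delta_FP * #FP summed over the three levels.
#'
#' @param zTrue,zPred [ContactMap-class] objects of identical dimensions.
#' @param h a [Hyperparameters-class].
#' @return numeric(1) loss; 0 iff the maps are identical.
#' @export
contactLoss <- function(zTrue, zPred, h = hyperParams()) {
  if (nResidues(zTrue) != nResidues(zPred) || nBases(zTrue) != nBases(zPred))
    .dataError("contact maps have different dimensions")
  it <- bindingIndicators(zTrue)
  ip <- bindingIndicators(zPred)
  keyOf <- function(m) (contacts(m)[, 1L] - 1L) * nBases(m) + contacts(m)[, 2L]
  kt <- keyOf(zTrue)
  kp <- keyOf(zPred)
  h@deltaFnResidue * sum(it$x == 1L & ip$x == 0L) +
    h@deltaFpResidue * sum(it$x == 0L & ip$x == 1L) +
    h@deltaFnBase * sum(it$y == 1L & ip$y == 0L) +
    h@deltaFpBase * sum(it$y == 0L & ip$y == 1L) +
    h@deltaFnContact * sum(!(kt %in% kp)) +
    h@deltaFpContact * sum(!(kp %in% kt))
}

#' Modify score terms for loss-augmented decoding
#'
#' Shifts each score so that decoding the modified problem maximizes
#' score + loss against the reference map: u_i loses delta_FN(residue)
#' where x_i = 1 and gains delta_FP(residue) where x_i = 0 (bases and
#' contacts analogous), and the constant offset
#' delta_FN(residue) * #bound residues + delta_FN(base) * #bound bases
#' + delta_FN(contact) * #contacts makes the identity exact:
#' augmented objective(z-hat) = score(z-hat) + loss(zTrue, z-hat) for
#' every candidate z-hat.
#'
#' @param terms plain [ScoreTerms-class] for the pair.
#' @param zTrue the reference [ContactMap-class].
#' @param h a [Hyperparameters-class].
#' @return A [ScoreTerms-class] with modified u, v, w and offset.
#' @export
lossAugment <- function(terms, zTrue, h = hyperParams()) {
  stopifnot(is(terms, "ScoreTerms"))
  if (length(terms@u) != nResidues(zTrue) || length(terms@v) != nBases(zTrue))
    .dataError("score terms and contact map have different dimensions")
  ind <- bindingIndicators(zTrue)
  u <- terms@u + ifelse(ind$x == 1L, -h@deltaFnResidue, h@deltaFpResidue)
  v <- terms@v + ifelse(ind$y == 1L, -h@deltaFnBase, h@deltaFpBase)
  w <- terms@w + h@deltaFpContact
  cm <- contacts(zTrue)
  if (nrow(cm) > 0L)
    w[cm] <- terms@w[cm] - h@deltaFnContact
  offset <- terms@offset + h@deltaFnResidue * sum(ind$x) +
    h@deltaFnBase * sum(ind$y) + h@deltaFnContact * nrow(cm)
  scoreTerms(u, v, w, offset = offset)
}

#' Check a contact map against the decoding constraints
#'
#' Verifies the cap constraints and the no-isolated-bound-base rule
#' (the indicator-link constraints hold by construction for any
#' [ContactMap-class]).
#'
#' @param map a [ContactMap-class].
#' @param Xcap,Ycap caps (scalar or per-position; `Inf` = unbounded).
#' @return character vector of violation descriptions; empty when the
#'   map is feasible.
#' @export
checkContactConstraints <- function(map, Xcap = Inf, Ycap = Inf) {
  nP <- nResidues(map)
  nR <- nBases(map)
  Xcap <- .capVector(Xcap, nP, "residue")
  Ycap <- .capVector(Ycap, nR, "base")
  cm <- contacts(map)
  out <- character(0)
  rowCount <- tabulate(cm[, 1L], nP)
  colCount <- tabulate(cm[, 2L], nR)
  over <- which(rowCount > Xcap)
  if (length(over) > 0L)
    out <- c(out, sprintf("residue %d exceeds cap (%d > %g)", over,
                          rowCount[over], Xcap[over]))
  over <- which(colCount > Ycap)
  if (length(over) > 0L)
    out <- c(out, sprintf("base %d exceeds cap (%d > %g)", over,
                          colCount[over], Ycap[over]))
  y <- as.integer(colCount > 0L)
  yl <- c(0L, y[-nR])
  yr <- c(y[-1L], 0L)
  iso <- which(y == 1L & yl == 0L & yr == 0L)
  if (length(iso) > 0L)
    out <- c(out, sprintf("bound base %d is isolated", iso))
  out
}
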