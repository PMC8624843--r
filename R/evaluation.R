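## Three-level evaluation of predicted contact maps.
##
## Predictions are assessed at the contact level (entries of z), the
## binding-residue level (derived x) and the binding-base level
## (derived y) by positive predictive value PPV = TP / (TP + FP),
## sensitivity SEN = TP / (TP + FN), and their harmonic mean F.  A
## metric whose denominator is zero is reported as 0 and flagged.

#' Confusion counts between a true and a predicted contact map
#'
#' @param zTrue,zPred [ContactMap-class] objects of identical
#'   dimensions.
#' @return data.frame with one row per level (`contact`, `residue`,
#'   `base`) and columns `tp`, `fp`, `fn`.
#' @export
confusionCounts <- function(zTrue, zPred) {
  if (nResidues(zTrue) != nResidues(zPred) || nBases(zTrue) != nBases(zPred))
    .dataError("contact maps have different dimensions")
  keyOf <- function(m) (contacts(m)[, 1L] - 1L) * nBases(m) + contacts(m)[, 2L]
  kt <- keyOf(zTrue)
  kp <- keyOf(zPred)
  it <- bindingIndicators(zTrue)
  ip <- bindingIndicators(zPred)
  data.frame(
    level = c("contact", "residue", "base"),
    tp = c(sum(kt %in% kp), sum(it$x == 1L & ip$x == 1L),
           sum(it$y == 1L & ip$y == 1L)),
    fp = c(sum(!(kp %in% kt)), sum(it$x == 0L & ip$x == 1L),
           sum(it$y == 0L & ip$y == 1L)),
    fn = c(sum(!(kt %in% kp)), sum(it$x == 1L & ip$x == 0L),
           sum(it$y == 1L & ip$y == 0L)),
    stringsAsFactors = FALSE)
}

#' PPV, SEN and F from confusion counts
#'
#' @param counts data.frame with columns `tp`, `fp`, `fn` (any number
#'   of rows; extra columns are preserved).
#' @return the input with columns `ppv`, `sen`, `f` and a logical
#'   `flagged` marking rows where any denominator was zero (the metric
#'   is then reported as 0 by convention).
#' @examples
#' ppvSenF(data.frame(tp = 2, fp = 1, fn = 2))  # PPV 2/3, SEN 1/2, F 4/7
#' @export
ppvSenF <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  dP <- counts$tp + counts$fp
  dS <- counts$tp + counts$fn
  ppv <- ifelse(dP > 0, counts$tp / dP, 0)
  sen <- ifelse(dS > 0, counts$tp / dS, 0)
  f <- ifelse(ppv + sen > 0, 2 * ppv * sen / (ppv + sen), 0)
  counts$ppv <- ppv
  counts$sen <- sen
  counts$f <- f
  counts$flagged <- dP == 0 | dS == 0
  counts
}

#' Aggregate metrics over a dataset of map pairs
#'
#' Macro aggregation (the default) averages per-pair metrics, excluding
#' at each level the pairs that are vacuous there (tp + fp + fn = 0,
#' nothing to assess); micro aggregation pools the confusion counts
#' over all pairs first and computes the metrics once.
#'
#' @param pairs nonempty list; each element a list with `truth` and
#'   `pred` ([ContactMap-class] objects).
#' @param mode `"macro"` or `"micro"`.
#' @return data.frame with columns `level`, `ppv`, `sen`, `f`,
#'   `n_pairs` (pairs contributing at that level) and `mode`.
#' @export
evaluateDataset <- function(pairs, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) .dataError("empty evaluation set")
  perPair <- lapply(pairs, function(p) confusionCounts(p$truth, p$pred))
  levels <- c("contact", "residue", "base")
  if (mode == "micro") {
    pooled <- Reduce(function(a, b) {
      a[, c("tp", "fp", "fn")] <- a[, c("tp", "fp", "fn")] +
        b[, c("tp", "fp", "fn")]
      a
    }, perPair)
    m <- ppvSenF(pooled)
    return(data.frame(level = levels, ppv = m$ppv, sen = m$sen, f = m$f,
                      n_pairs = length(pairs), mode = mode,
                      stringsAsFactors = FALSE))
  }
  out <- lapply(levels, function(lv) {
    rows <- do.call(rbind, lapply(perPair, function(cc) cc[cc$level == lv, ]))
    use <- rows$tp + rows$fp + rows$fn > 0
    if (!any(use))
      return(data.frame(level = lv, ppv = NA_real_, sen = NA_real_,
                        f = NA_real_, n_pairs = 0L, mode = mode,
                        stringsAsFactors = FALSE))
    m <- ppvSenF(rows[use, ])
    data.frame(level = lv, ppv = mean(m$ppv), sen = mean(m$sen),
               f = mean(m$f), n_pairs = sum(use), mode = mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
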