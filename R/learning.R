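## Structured-SVM training by stochastic subgradient descent.
##
## The learner minimizes, over sparse weights lambda,
##   sum_k [ max_zhat ( f(zhat) + loss(z_k, zhat) ) - f(z_k) ] + C ||lambda||_1,
## where the inner max is computed exactly by loss-augmented IP
## decoding.  Each visit to an instance takes one subgradient step
## phi(zhat) - phi(z_k) + C sgn(lambda) with per-coordinate AdaGrad
## step sizes eta / sqrt(G_k + eps), G_k accumulating squared
## subgradients.  The l1 subgradient applies to every materialized
## weight (sgn(0) = 0), so untouched keys never move.

#' One AdaGrad subgradient step over a set of keys
#'
#' Updates `state$w[keys] <- w - eta / sqrt(G + eps) * grad` after
#' accumulating `G <- G + grad^2`.  Keys not yet materialized enter at
#' weight 0 with accumulator 0.  A zero gradient leaves both the weight
#' and the accumulator unchanged.
#'
#' @param state list with named numeric vectors `w` and `G` (aligned
#'   names) and scalars `eta`, `epsilon`.
#' @param keys character vector of feature keys.
#' @param grads numeric vector of subgradients, parallel to `keys`.
#' @return the updated state.
#' @export
adagradStep <- function(state, keys, grads) {
  stopifnot(length(keys) == length(grads), all(is.finite(grads)))
  live <- grads != 0
  keys <- keys[live]
  grads <- grads[live]
  if (length(keys) == 0L) return(state)
  newKeys <- setdiff(keys, names(state$w))
  if (length(newKeys) > 0L) {
    state$w <- c(state$w, stats::setNames(numeric(length(newKeys)), newKeys))
    state$G <- c(state$G, stats::setNames(numeric(length(newKeys)), newKeys))
  }
  idx <- match(keys, names(state$w))
  G <- state$G[idx] + grads^2
  state$G[idx] <- G
  state$w[idx] <- state$w[idx] - state$eta / sqrt(G + state$epsilon) * grads
  state$maxChange <- max(state$maxChange,
                         abs(state$eta / sqrt(G + state$epsilon) * grads))
  state
}

## sparse difference of two named count vectors
.sparseDiff <- function(a, b) {
  keys <- union(names(a), names(b))
  if (length(keys) == 0L) return(stats::setNames(numeric(0), character(0)))
  av <- a[match(keys, names(a))]
  av[is.na(av)] <- 0
  bv <- b[match(keys, names(b))]
  bv[is.na(bv)] <- 0
  stats::setNames(as.numeric(av - bv), keys)
}

## per-instance precomputation: all key strings plus the truth features
.prepInstance <- function(inst, config) {
  keys <- .scoreTermKeys(inst@protein, inst@rna, config)
  list(keys = keys,
       phiTrue = fullFeatures(inst@protein, inst@rna, inst@map, config),
       zTrue = inst@map, id = inst@protein@id)
}

## feature counts of an arbitrary map from precomputed keys (avoids
## rebuilding window strings inside the training loop)
.phiFromKeys <- function(keys, map) {
  ind <- bindingIndicators(map)
  px <- which(ind$x == 1L)
  py <- which(ind$y == 1L)
  cm <- contacts(map)
  cellIdx <- if (nrow(cm) > 0L) (cm[, 2L] - 1L) * keys$nP + cm[, 1L] else integer(0)
  all <- c(unlist(lapply(keys$u, `[`, px), use.names = FALSE),
           unlist(lapply(keys$v, `[`, py), use.names = FALSE),
           unlist(lapply(keys$w, `[`, cellIdx), use.names = FALSE))
  .countKeys(all)
}

#' Structured-SVM training objective
#'
#' Evaluates the regularized hinge objective at fixed weights: for each
#' instance the exact loss-augmented maximum minus the score of the
#' true map, plus C times the l1 norm of the weights.  The inner
#' maxima for all instances are decoded in one backend call.
#'
#' @param instances list of [TrainingInstance-class] objects.
#' @param model a [ModelWeights-class].
#' @param h a [Hyperparameters-class] (loss penalties, C, caps).
#' @param config a [FeatureConfig-class].
#' @param solver IP backend, see [predictContactsBatch()].
#' @return numeric(1) objective value (nonnegative whenever every true
#'   map is feasible under the caps).
#' @export
svmObjective <- function(instances, model, h = hyperParams(),
                         config = featureConfig(),
                         solver = getOption("PRIcontact.solver", "highs")) {
  stopifnot(length(instances) > 0L)
  problems <- lapply(instances, function(inst) {
    terms <- computeScoreTerms(inst@protein, inst@rna, model, config)
    list(terms = lossAugment(terms, inst@map, h))
  })
  sols <- predictContactsBatch(problems, Xcap = h@Xcap, Ycap = h@Ycap,
                               solver = solver)
  hinge <- vapply(seq_along(instances), function(k) {
    inst <- instances[[k]]
    sols[[k]]$objective -
      scoreContactMap(inst@protein, inst@rna, inst@map, model, config)
  }, numeric(1))
  sum(hinge) + h@C * sum(abs(featureWeights(model)))
}

#' Train model weights by stochastic subgradient descent with AdaGrad
#'
#' Iterates over the training set (order shuffled per epoch under the
#' seed), decodes the loss-augmented argmax for the visited instance,
#' and takes one AdaGrad-scaled subgradient step on the keys of the
#' decoded and true feature vectors plus the l1 term on all
#' materialized keys.  Training stops when the maximum absolute weight
#' change within an epoch falls below `h@tol`, when an epoch incurs
#' zero hinge (every instance decoded to its true map with margin), or
#' at `h@maxEpochs`.  The run is deterministic given the seed.
#'
#' Every true map must satisfy the cap and isolated-base constraints;
#' infeasible gold maps are reported by instance id.  Setting
#' `capsInAugment = FALSE` drops the caps during the loss-augmented max
#' (they are still enforced at prediction time).
#'
#' @param instances list of [TrainingInstance-class] objects (nonempty).
#' @param h a [Hyperparameters-class].
#' @param config a [FeatureConfig-class].
#' @param seed integer seed for the per-epoch shuffles.
#' @param shuffle shuffle instance order each epoch (default TRUE).
#' @param capsInAugment enforce the caps inside loss-augmented decoding.
#' @param solver IP backend, see [predictContactsBatch()].
#' @param verbose print one line per epoch.
#' @return list with `model` (a [ModelWeights-class], exact zeros
#'   pruned), `history` (data.frame: epoch, hinge, maxChange,
#'   nonzero), `epochs` and `converged`.
#' @export
trainModel <- function(instances, h = hyperParams(), config = featureConfig(),
                       seed = 1L, shuffle = TRUE, capsInAugment = TRUE,
                       solver = getOption("PRIcontact.solver", "highs"),
                       verbose = FALSE) {
  if (length(instances) == 0L) .dataError("empty training set")
  for (inst in instances) {
    viol <- checkContactConstraints(inst@map, h@Xcap, h@Ycap)
    if (length(viol) > 0L)
      .dataError(sprintf("true contact map of instance '%s' is infeasible under the caps: %s",
                         inst@protein@id, viol[1L]))
  }
  prep <- lapply(instances, .prepInstance, config = config)
  n <- length(prep)
  augXcap <- if (capsInAugment) h@Xcap else Inf
  augYcap <- if (capsInAugment) h@Ycap else Inf

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  state <- list(w = stats::setNames(numeric(0), character(0)),
                G = stats::setNames(numeric(0), character(0)),
                eta = h@eta, epsilon = h@epsilon, maxChange = 0)
  history <- data.frame(epoch = integer(0), hinge = numeric(0),
                        maxChange = numeric(0), nonzero = integer(0))
  converged <- FALSE
  epoch <- 0L
  while (epoch < h@maxEpochs) {
    epoch <- epoch + 1L
    state$maxChange <- 0
    hingeSum <- 0
    order <- if (shuffle) sample.int(n) else seq_len(n)
    for (k in order) {
      p <- prep[[k]]
      model <- modelWeightsUnsafe(state$w)
      terms <- .termsFromKeys(p$keys, model)
      aug <- lossAugment(terms, p$zTrue, h)
      sol <- predictContactsBatch(list(list(terms = aug)),
                                  Xcap = augXcap, Ycap = augYcap,
                                  solver = solver)[[1L]]
      phiHat <- .phiFromKeys(p$keys, sol$map)
      fTrue <- {
        wv <- .lookupWeights(model, names(p$phiTrue))
        sum(wv * p$phiTrue)
      }
      hingeSum <- hingeSum + (sol$objective - fTrue)
      gSparse <- .sparseDiff(phiHat, p$phiTrue)
      allKeys <- union(names(gSparse), names(state$w))
      g <- numeric(length(allKeys))
      gi <- match(names(gSparse), allKeys)
      g[gi] <- gSparse
      wi <- match(names(state$w), allKeys)
      g[wi] <- g[wi] + h@C * sign(state$w)
      state <- adagradStep(state, allKeys, g)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, hinge = hingeSum,
                                maxChange = state$maxChange,
                                nonzero = sum(state$w != 0)))
    if (verbose)
      message(sprintf("epoch %3d  hinge %.6g  max|dw| %.3g  nnz %d",
                      epoch, hingeSum, state$maxChange, sum(state$w != 0)))
    if (state$maxChange < h@tol || hingeSum <= 1e-12) {
      converged <- TRUE
      break
    }
  }
  list(model = modelWeights(state$w), history = history,
       epochs = epoch, converged = converged)
}

## internal: wrap weights without the (costly) zero-pruning/validity of
## modelWeights(); zeros behave as absent keys in every lookup
modelWeightsUnsafe <- function(w) {
  obj <- new("ModelWeights", w = w[w != 0])
  obj
}
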