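## Accessor generics and show methods.

#' Number of residues / bases of a contact map
#'
#' @param x a [ContactMap-class] (or [TrainingInstance-class]).
#' @return integer(1).
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname nResidues
#' @export
setGeneric("nBases", function(x) standardGeneric("nBases"))

#' Contact index pairs of a ContactMap
#'
#' @param x a [ContactMap-class].
#' @return integer matrix with columns (residue, base), 1-based.
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' Derived binding-site indicators of a contact map
#'
#' x_i = 1 iff residue i participates in at least one contact; y_j = 1
#' iff base j does.  This derivation is idempotent and is exactly the
#' consistency relation the IP constraints enforce between z, x and y.
#'
#' @param x a [ContactMap-class].
#' @return list with integer vectors `x` (length |P|) and `y` (length |R|).
#' @examples
#' bindingIndicators(contactMap(cbind(1, 2), 2, 3))
#' @export
setGeneric("bindingIndicators", function(x) standardGeneric("bindingIndicators"))

#' Sparse weights of a ModelWeights object
#'
#' @param x a [ModelWeights-class].
#' @return named numeric vector of nonzero weights.
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "ContactMap", function(x) x@nResidues)

#' @rdname nResidues
#' @export
setMethod("nBases", "ContactMap", function(x) x@nBases)

#' @rdname nResidues
#' @export
setMethod("nResidues", "TrainingInstance", function(x) x@map@nResidues)

#' @rdname nResidues
#' @export
setMethod("nBases", "TrainingInstance", function(x) x@map@nBases)

#' @rdname contacts
#' @export
setMethod("contacts", "ContactMap", function(x) x@contacts)

#' @rdname bindingIndicators
#' @export
setMethod("bindingIndicators", "ContactMap", function(x) {
  xi <- integer(x@nResidues)
  yj <- integer(x@nBases)
  if (nrow(x@contacts) > 0L) {
    xi[unique(x@contacts[, 1L])] <- 1L
    yj[unique(x@contacts[, 2L])] <- 1L
  }
  list(x = xi, y = yj)
})

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "ModelWeights", function(x) x@w)

#' @describeIn featureWeights number of stored (nonzero) weights.
#' @export
setMethod("length", "ModelWeights", function(x) length(x@w))

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord '%s' (%d residues)\n", object@id,
              nchar(object@sequence)))
  cat("  seq: ", object@sequence, "\n  ss8: ", object@ss8, "\n", sep = "")
})

setMethod("show", "RNARecord", function(object) {
  cat(sprintf("RNARecord '%s' (%d bases)\n", object@id,
              nchar(object@sequence)))
  cat("  seq:     ", object@sequence, "\n  struct:  ", object@dotbracket,
      "\n  profile: ", object@profile, "\n", sep = "")
})

setMethod("show", "ContactMap", function(object) {
  ind <- bindingIndicators(object)
  cat(sprintf("ContactMap %d x %d: %d contacts, %d binding residues, %d binding bases\n",
              object@nResidues, object@nBases, nrow(object@contacts),
              sum(ind$x), sum(ind$y)))
  if (nrow(object@contacts) > 0L) {
    shown <- utils::head(object@contacts, 6L)
    cat("  ", paste(sprintf("(%d,%d)", shown[, 1L], shown[, 2L]),
                    collapse = " "),
        if (nrow(object@contacts) > 6L) " ..." else "", "\n", sep = "")
  }
})

setMethod("show", "ModelWeights", function(object) {
  cat(sprintf("ModelWeights: %d nonzero features\n", length(object@w)))
  if (length(object@w) > 0L) {
    top <- utils::head(object@w[order(-abs(object@w))], 3L)
    for (i in seq_along(top))
      cat(sprintf("  %-40s %+.4g\n", gsub("\t", " | ", names(top)[i]), top[i]))
  }
})

setMethod("show", "TrainingInstance", function(object) {
  cat(sprintf("TrainingInstance '%s': |P|=%d, |R|=%d, %d contacts\n",
              object@protein@id, nResidues(object), nBases(object),
              nrow(object@map@contacts)))
})
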