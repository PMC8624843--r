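## File readers and writers.  All formats are plain text: FASTA for
## sequences, one-line-per-record TSV annotations (id <TAB> string) for
## ss8 / dot-bracket strings, two-column TSV for contact maps, and a
## TSV model format (feature_type, context1, context2, weight).

.fastaLineOfRecord <- function(path, recordIndex) {
  ## best-effort line number of a record's header, for error messages
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  hdr <- grep("^>", lines)
  if (recordIndex <= length(hdr)) hdr[recordIndex] else NA_integer_
}

.readFasta <- function(path, mode = c("protein", "rna")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) .dataError(paste0("FASTA file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("FASTA parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  if (mode == "rna") seqs <- chartr("T", "U", seqs)
  alphabet <- if (mode == "rna") RNA_ALPHABET else AA_ALPHABET
  for (r in seq_along(seqs)) {
    m <- .checkAlphabet(seqs[r], alphabet, sprintf("record '%s'", ids[r]))
    if (!is.null(m)) {
      ln <- .fastaLineOfRecord(path, r)
      stop(sprintf("FASTA parse error in '%s' (record starting at line %s): %s",
                   path, ifelse(is.na(ln), "?", ln), m))
    }
  }
  stats::setNames(seqs, ids)
}

#' Read protein or RNA sequences from a FASTA file
#'
#' Sequences are upper-cased; in RNA mode `T` is mapped to `U`.
#' Characters outside the canonical alphabet (20 amino-acid letters, or
#' ACGU) are rejected with a parse error naming the record and line.
#'
#' @param path FASTA file path.
#' @return named character vector (id -> sequence) in file order.
#' @export
readProteinFasta <- function(path) .readFasta(path, "protein")

#' @rdname readProteinFasta
#' @export
readRnaFasta <- function(path) .readFasta(path, "rna")

#' Read a one-line-per-record annotation file
#'
#' Format: `id<TAB>string`, one record per line, used for ss8 strings
#' and dot-bracket strings keyed by FASTA record id.
#'
#' @param path annotation file path.
#' @return named character vector (id -> string).
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) .dataError(paste0("annotation file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("annotation parse error in '%s' at line %d: expected 'id<TAB>string'",
                 path, bad[1L]))
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

#' @rdname readAnnotations
#' @param x named character vector (id -> string).
#' @export
writeAnnotations <- function(x, path) {
  writeLines(paste(names(x), x, sep = "\t"), path)
}

#' Read / write a sparse contact map as two-column TSV
#'
#' Rows are 1-based `(residue index, base index)` pairs; duplicates are
#' collapsed on read; out-of-range indices raise a bounds error citing
#' the offending row.
#'
#' @param path TSV file path.
#' @param nResidues,nBases dimensions of the map.
#' @return A [ContactMap-class].
#' @export
readContactMap <- function(path, nResidues, nBases) {
  if (!file.exists(path)) .dataError(paste0("contact map file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(contactMap(nResidues = nResidues, nBases = nBases))
  tab <- utils::read.table(text = lines, sep = "\t",
                           colClasses = c("integer", "integer"),
                           col.names = c("i", "j"))
  badI <- which(tab$i < 1L | tab$i > nResidues)
  badJ <- which(tab$j < 1L | tab$j > nBases)
  if (length(badI) > 0L)
    stop(sprintf("contact map bounds error in '%s' at row %d: residue index %d outside [1, %d]",
                 path, badI[1L], tab$i[badI[1L]], nResidues))
  if (length(badJ) > 0L)
    stop(sprintf("contact map bounds error in '%s' at row %d: base index %d outside [1, %d]",
                 path, badJ[1L], tab$j[badJ[1L]], nBases))
  contactMap(cbind(tab$i, tab$j), nResidues, nBases)
}

#' @rdname readContactMap
#' @param map a [ContactMap-class].
#' @export
writeContactMap <- function(map, path) {
  stopifnot(is(map, "ContactMap"))
  cm <- contacts(map)
  writeLines(if (nrow(cm) == 0L) character(0)
             else paste(cm[, 1L], cm[, 2L], sep = "\t"), path)
}

## ---- model TSV ----

.knownFeatureTypes <- function(config = featureConfig()) {
  c(config@residueRows$type, config@baseRows$type, config@contactRows$type)
}

#' Read / write model weights as TSV
#'
#' Format: `feature_type <TAB> context1 <TAB> context2 <TAB> weight`,
#' with `context2` empty for unary (residue/base) features.  Weights
#' are written at full precision so that write/read round-trips are
#' exact; exact zeros are pruned on read.  Unknown feature-type tags
#' raise a format error.
#'
#' @param path TSV file path.
#' @param config the [FeatureConfig-class] defining the legal feature
#'   type tags.
#' @return A [ModelWeights-class].
#' @export
readModel <- function(path, config = featureConfig()) {
  if (!file.exists(path)) .dataError(paste0("model file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(modelWeights())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L)
    stop(sprintf("model format error in '%s' at line %d: expected 4 tab-separated fields",
                 path, bad[1L]))
  type <- vapply(parts, `[`, character(1), 1L)
  unknown <- which(!(type %in% .knownFeatureTypes(config)))
  if (length(unknown) > 0L)
    stop(sprintf("model format error in '%s' at line %d: unknown feature type '%s'",
                 path, unknown[1L], type[unknown[1L]]))
  ctx1 <- vapply(parts, `[`, character(1), 2L)
  ctx2 <- vapply(parts, `[`, character(1), 3L)
  isContact <- type %in% config@contactRows$type
  if (any(isContact & ctx2 == ""))
    stop(sprintf("model format error in '%s': contact feature missing second context", path))
  if (any(!isContact & ctx2 != ""))
    stop(sprintf("model format error in '%s': unary feature with second context", path))
  w <- as.numeric(vapply(parts, `[`, character(1), 4L))
  keys <- ifelse(isContact, paste(type, ctx1, ctx2, sep = "\t"),
                 paste(type, ctx1, sep = "\t"))
  modelWeights(stats::setNames(w, keys))
}

#' @rdname readModel
#' @param model a [ModelWeights-class].
#' @export
writeModel <- function(model, path, config = featureConfig()) {
  stopifnot(is(model, "ModelWeights"))
  w <- featureWeights(model)
  if (length(w) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  parts <- strsplit(names(w), "\t", fixed = TRUE)
  type <- vapply(parts, `[`, character(1), 1L)
  ctx1 <- vapply(parts, `[`, character(1), 2L)
  ctx2 <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "",
                 character(1))
  ord <- order(type, ctx1, ctx2)
  writeLines(paste(type[ord], ctx1[ord], ctx2[ord],
                   sprintf("%.17g", w[ord]), sep = "\t"), path)
  invisible(path)
}
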