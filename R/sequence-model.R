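#' Construct a ProteinSequence
#'
#' @param id Sequence identifier.
#' @param residues One-letter amino acid string; lowercase input is
#'   uppercased. Only the 20 canonical codes plus \code{X} are accepted.
#' @param offset 1-based parent-protein position of the first residue.
#' @param description Optional free-text description.
#' @return A [ProteinSequence-class] object.
#' @examples
#' camkii <- proteinSequence("CaMKIIA", "RRKLKGAILTTMLATR", offset = 296)
#' camkii
#' @export
proteinSequence <- function(id, residues, offset = 1L, description = "") {
  new("ProteinSequence", id = as.character(id),
      residues = toupper(as.character(residues)),
      offset = as.integer(offset), description = as.character(description))
}

#' Construct a SequenceRegion
#'
#' @param parentId Identifier of the parent sequence.
#' @param start,end 1-based inclusive bounds in parent coordinates.
#' @return A [SequenceRegion-class] object.
#' @export
sequenceRegion <- function(parentId, start, end) {
  new("SequenceRegion", parentId = as.character(parentId),
      start = as.integer(start), end = as.integer(end))
}

#' @describeIn proteinSequence Number of residues.
#' @param x A ProteinSequence.
#' @export
setMethod("length", "ProteinSequence", function(x) nchar(x@residues))

#' Accessors for ProteinSequence
#'
#' `seqId()`, `seqOffset()` and `residues()` read the identifier, numbering
#' offset and residue string; `seqEnd()` gives the parent position of the
#' last residue (`offset + length - 1`).
#'
#' @param x A [ProteinSequence-class].
#' @return The corresponding slot value (scalar).
#' @name ProteinSequence-accessors
NULL

#' @rdname ProteinSequence-accessors
#' @export
seqId <- function(x) x@id

#' @rdname ProteinSequence-accessors
#' @export
seqOffset <- function(x) x@offset

#' @rdname ProteinSequence-accessors
#' @export
residues <- function(x) x@residues

#' @rdname ProteinSequence-accessors
#' @export
seqEnd <- function(x) x@offset + nchar(x@residues) - 1L

setMethod("show", "ProteinSequence", function(object) {
  n <- nchar(object@residues)
  res <- if (n > 40L)
    paste0(substr(object@residues, 1L, 37L), "...")
  else object@residues
  cat(sprintf("ProteinSequence '%s': %d aa, positions %d-%d\n  %s\n",
              object@id, n, object@offset, seqEnd(object), res))
})

setMethod("show", "SequenceRegion", function(object) {
  cat(sprintf("SequenceRegion %s:%d-%d (%d aa)\n", object@parentId,
              object@start, object@end, object@end - object@start + 1L))
})

## split a residue string into a character vector, one letter per residue
.residueVector <- function(seq) strsplit(seq@residues, "", fixed = TRUE)[[1L]]

#' Read protein sequences from a FASTA file
#'
#' Each record becomes one [ProteinSequence-class]. The numbering offset
#' defaults to 1 unless the header carries a token \code{start=<n>}
#' (e.g. \code{>camkiia start=296}), which is removed from the stored
#' description. Lowercase residues are uppercased; gap characters and any
#' letter outside the 20 canonical codes plus \code{X} are rejected with an
#' error naming the record and position.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return A named list of [ProteinSequence-class] objects.
#' @seealso [writeProteinFasta()]
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(trimws(header), "\\s+")[[1L]]
    id <- toks[1L]
    rest <- toks[-1L]
    offset <- 1L
    hit <- grepl("^start=\\d+$", rest)
    if (any(hit)) {
      offset <- as.integer(sub("^start=", "", rest[which(hit)[1L]]))
      rest <- rest[!hit]
    }
    res <- toupper(as.character(set[[i]]))
    ch <- strsplit(res, "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% .AA_ALLOWED))
    if (length(bad))
      stop(sprintf("record '%s': illegal residue '%s' at position %d",
                   id, ch[bad[1L]], bad[1L]))
    out[[i]] <- proteinSequence(id, res, offset = offset,
                                description = paste(rest, collapse = " "))
  }
  names(out) <- vapply(out, seqId, character(1L))
  out
}

#' Write protein sequences to a FASTA file
#'
#' The numbering offset is encoded in the header as \code{start=<n>} so
#' that [readProteinFasta()] round-trips id, residues and offset.
#'
#' @param seqs A ProteinSequence or list of ProteinSequence objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is(seqs, "ProteinSequence")) seqs <- list(seqs)
  headers <- vapply(seqs, function(s) {
    h <- sprintf("%s start=%d", s@id, s@offset)
    if (nzchar(s@description)) h <- paste(h, s@description)
    h
  }, character(1L))
  set <- Biostrings::BStringSet(vapply(seqs, residues, character(1L)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract a region of a protein in parent coordinates
#'
#' @param seq A [ProteinSequence-class].
#' @param region A [SequenceRegion-class] in the same parent coordinate
#'   frame; must lie within the bounds of `seq`.
#' @return A [ProteinSequence-class] whose offset is `region@start`.
#' @examples
#' s <- proteinSequence("x", "MKLRRKLKGAILTTMLATR", offset = 290)
#' extractRegion(s, sequenceRegion("x", 296, 305))
#' @export
extractRegion <- function(seq, region) {
  stopifnot(is(seq, "ProteinSequence"), is(region, "SequenceRegion"))
  if (!identical(region@parentId, seq@id))
    stop(sprintf("region parent '%s' does not match sequence '%s'",
                 region@parentId, seq@id))
  lo <- seq@offset
  hi <- seqEnd(seq)
  if (region@start < lo || region@end > hi)
    stop(sprintf("region %d-%d out of bounds for '%s' (%d-%d)",
                 region@start, region@end, seq@id, lo, hi))
  i <- region@start - lo + 1L
  j <- region@end - lo + 1L
  proteinSequence(seq@id, substr(seq@residues, i, j), offset = region@start,
                  description = seq@description)
}
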