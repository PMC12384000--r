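#' Built-in canonical motif classes
#'
#' The canonical calcium-dependent calmodulin-binding motif classes defined
#' by anchor spacing: two-anchor classes 1-10, 1-12, 1-14, 1-16 and
#' three-anchor refinements 1-5-10 (of 1-10), 1-8-14 (of 1-14) and 1-8-13
#' (no parent). Positions are counted inclusively from the first anchor, so
#' "1-5-10" means 0-based offsets 0, 4, 9.
#'
#' @param names Optional character vector selecting a subset by name.
#' @return A named list of [MotifClass-class] objects.
#' @examples
#' motifClasses(c("1-5-10", "1-10"))
#' @export
motifClasses <- function(names = NULL) {
  mk <- function(offsets, parent = NA_character_) {
    offsets <- as.integer(offsets)
    new("MotifClass", name = paste(offsets + 1L, collapse = "-"),
        anchorOffsets = offsets, parent = parent)
  }
  all <- list(
    mk(c(0, 9)),
    mk(c(0, 11)),
    mk(c(0, 13)),
    mk(c(0, 15)),
    mk(c(0, 4, 9), parent = "1-10"),
    mk(c(0, 7, 12)),
    mk(c(0, 7, 13), parent = "1-14")
  )
  names(all) <- vapply(all, function(x) x@name, character(1L))
  if (is.null(names)) return(all)
  missing <- setdiff(names, base::names(all))
  if (length(missing))
    stop("unknown motif class(es): ", paste(missing, collapse = ", "))
  all[names]
}

#' Built-in anchor residue sets
#'
#' `core` is the canonical anchor hydrophobic set Phe, Ile, Leu, Val, Trp.
#' `extended` adds Met and Tyr, needed to reach some curated fingerprints
#' (e.g. motifs whose terminal anchor is a methionine).
#'
#' @param name "core" (default) or "extended".
#' @return An [AnchorSet-class] object.
#' @export
anchorSet <- function(name = c("core", "extended")) {
  name <- match.arg(name)
  letters <- switch(name,
    core = c("F", "I", "L", "V", "W"),
    extended = c("F", "I", "L", "V", "W", "M", "Y"))
  new("AnchorSet", name = name, letters = letters)
}

## empty match table with the canonical column layout
.emptyMatches <- function() {
  S4Vectors::DataFrame(
    seq_id = character(0), class_name = character(0),
    anchor_positions = IRanges::IntegerList(),
    fingerprint = character(0),
    span_start = integer(0), span_end = integer(0))
}

.sortMatches <- function(m) {
  if (nrow(m) == 0L) return(m)
  span <- m$span_end - m$span_start + 1L
  m[order(m$span_start, span, m$class_name), , drop = FALSE]
}

#' Enumerate raw anchor-spacing motif matches
#'
#' Exhaustive scan: for every motif class and every start position such
#' that all anchor offsets fall within the sequence and land on anchor-set
#' residues, one match is emitted. No curation is applied; use
#' [applySubsumption()] or [scanMotifs()] with `mode = "curated"` to
#' suppress two-anchor matches coterminal with a refining three-anchor
#' match. Anchor positions are reported in parent-protein coordinates.
#'
#' @param seq A [ProteinSequence-class].
#' @param classes A list of [MotifClass-class] objects
#'   (default [motifClasses()]).
#' @param anchors An [AnchorSet-class] (default core).
#' @return A `DataFrame` with columns seq_id, class_name, anchor_positions
#'   (an `IntegerList`), fingerprint, span_start, span_end, sorted by
#'   (span_start, span length, class name).
#' @examples
#' camkii <- proteinSequence("CaMKIIA", "RRKLKGAILTTMLATR", offset = 296)
#' enumerateMatches(camkii)
#' @export
enumerateMatches <- function(seq, classes = motifClasses(),
                             anchors = anchorSet("core")) {
  stopifnot(is(seq, "ProteinSequence"), is(anchors, "AnchorSet"))
  if (length(classes) == 0L) stop("'classes' must be non-empty")
  ch <- .residueVector(seq)
  n <- length(ch)
  isAnchor <- ch %in% anchors@letters
  rows <- list()
  for (cl in classes) {
    off <- cl@anchorOffsets
    span <- off[length(off)] + 1L
    if (span > n) next
    starts <- seq_len(n - span + 1L)
    ok <- rep(TRUE, length(starts))
    for (o in off) ok <- ok & isAnchor[starts + o]
    for (s in starts[ok]) {
      idx <- s + off
      rows[[length(rows) + 1L]] <- list(
        class_name = cl@name,
        anchor_positions = seq@offset + idx - 1L,
        fingerprint = paste(ch[idx], collapse = ""),
        span_start = seq@offset + s - 1L,
        span_end = seq@offset + s + span - 2L)
    }
  }
  if (length(rows) == 0L) return(.emptyMatches())
  m <- S4Vectors::DataFrame(
    seq_id = rep(seq@id, length(rows)),
    class_name = vapply(rows, `[[`, character(1L), "class_name"),
    anchor_positions = IRanges::IntegerList(
      lapply(rows, `[[`, "anchor_positions")),
    fingerprint = vapply(rows, `[[`, character(1L), "fingerprint"),
    span_start = vapply(rows, function(r) as.integer(r$span_start), integer(1L)),
    span_end = vapply(rows, function(r) as.integer(r$span_end), integer(1L)))
  .sortMatches(m)
}

#' Suppress two-anchor matches subsumed by a refining three-anchor match
#'
#' Curation rule reconciling exhaustive scans with visually curated motif
#' lists: a two-anchor match whose terminal anchor pair coincides with the
#' first and last anchors of a reported three-anchor match of its refining
#' class (1-10 under a coterminal 1-5-10; 1-14 under a coterminal 1-8-14)
#' is removed. All other matches pass through unchanged; nothing is added.
#'
#' @param matches A match table from [enumerateMatches()].
#' @param classes The motif class list in use (supplies the parent map).
#' @return The curated match table, same columns and sort order.
#' @export
applySubsumption <- function(matches, classes = motifClasses()) {
  if (nrow(matches) == 0L) return(matches)
  parentOf <- vapply(classes, function(x) x@parent, character(1L))
  names(parentOf) <- vapply(classes, function(x) x@name, character(1L))
  ap <- as.list(matches$anchor_positions)
  first <- vapply(ap, function(p) p[1L], integer(1L))
  last <- vapply(ap, function(p) p[length(p)], integer(1L))
  nAnchor <- lengths(ap)
  ## terminal-anchor keys of emitted refining (3-anchor) matches, per parent
  refKeys <- split(
    paste(matches$seq_id, first, last)[nAnchor >= 3L],
    parentOf[matches$class_name][nAnchor >= 3L])
  drop <- rep(FALSE, nrow(matches))
  for (parent in names(refKeys)) {
    if (is.na(parent)) next
    cand <- nAnchor == 2L & matches$class_name == parent
    drop <- drop | (cand &
      paste(matches$seq_id, first, last) %in% refKeys[[parent]])
  }
  matches[!drop, , drop = FALSE]
}

#' Scan a sequence for canonical calmodulin-binding motifs
#'
#' Convenience wrapper: [enumerateMatches()] followed, in the default
#' curated mode, by [applySubsumption()]. Curated mode reproduces visually
#' curated motif counts on peptides where the raw scan reports both a
#' three-anchor motif and its embedded coterminal two-anchor form.
#'
#' @inheritParams enumerateMatches
#' @param mode "curated" (default) or "raw".
#' @return A match table; see [enumerateMatches()].
#' @examples
#' tgm2 <- proteinSequence("TGM2-CaMBD1", "KSINRSLIVGLKISTKSVGR", offset = 414)
#' scanMotifs(tgm2)                 # curated: 1-16, 1-12, 1-5-10
#' scanMotifs(tgm2, mode = "raw")   # also reports the subsumed 1-10
#' @export
scanMotifs <- function(seq, classes = motifClasses(),
                       anchors = anchorSet("core"),
                       mode = c("curated", "raw")) {
  mode <- match.arg(mode)
  m <- enumerateMatches(seq, classes, anchors)
  if (mode == "curated") m <- applySubsumption(m, classes)
  m
}

## IQ motif: [FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]; x = any residue.
## X (unknown) never satisfies a bracketed class but is allowed at x.
.IQ_PATTERN <- "[FILV]Q[A-Z]{3}[RK]G[A-Z]{3}[RK][A-Z]{2}[FILVWY]"

#' Scan for IQ motifs (calcium-independent calmodulin binding)
#'
#' Finds all, possibly overlapping, 14-residue windows matching the IQ
#' pattern \code{[FILV]Qxxx[RK]Gxxx[RK]xx[FILVWY]} where \code{x} is any
#' residue. \code{X} is accepted at wildcard positions but never matches a
#' bracketed class.
#'
#' @param seq A [ProteinSequence-class].
#' @return A `DataFrame` with columns seq_id, start (1-based parent
#'   position) and matched (the 14-residue window).
#' @examples
#' scanIQ(proteinSequence("toy", "IQAAARGAAARAAF"))
#' @export
scanIQ <- function(seq) {
  stopifnot(is(seq, "ProteinSequence"))
  ## lookahead so overlapping windows are all reported
  hits <- gregexpr(paste0("(?=", .IQ_PATTERN, ")"), seq@residues,
                   perl = TRUE)[[1L]]
  if (hits[1L] == -1L)
    return(S4Vectors::DataFrame(seq_id = character(0), start = integer(0),
                                matched = character(0)))
  starts <- as.integer(hits)
  S4Vectors::DataFrame(
    seq_id = rep(seq@id, length(starts)),
    start = seq@offset + starts - 1L,
    matched = substring(seq@residues, starts, starts + 13L))
}

#' Tabulate anchor fingerprints per motif class
#'
#' The fingerprint of a match is the ordered string of its anchor residue
#' letters (e.g. "LIL" for a 1-5-10 motif anchored by Leu, Ile, Leu).
#' Fingerprints are grouped by class with duplicates collapsed.
#'
#' @param matches A match table from [scanMotifs()] or [enumerateMatches()].
#' @return A named list mapping class name to a sorted character vector of
#'   distinct fingerprints; empty list for an empty match table.
#' @export
fingerprintTable <- function(matches) {
  if (nrow(matches) == 0L) return(setNames(list(), character(0)))
  lapply(split(matches$fingerprint, matches$class_name),
         function(x) sort(unique(x)))
}

#' Compare anchor fingerprints between two proteins
#'
#' Per-class set algebra on fingerprint tables, the basis for asking
#' whether two calmodulin-binding proteins use the same key anchor
#' residues. Classes absent from one table are treated as empty.
#'
#' @param a,b Fingerprint tables from [fingerprintTable()].
#' @return A named list, one entry per class present in either table, each
#'   a list with elements `shared`, `only_a`, `only_b`.
#' @examples
#' camkii <- list("1-5-10" = "LIL")
#' gsk3b <- list("1-5-10" = "ILF")
#' compareFingerprints(camkii, gsk3b)
#' @export
compareFingerprints <- function(a, b) {
  classes <- sort(union(names(a), names(b)))
  out <- lapply(classes, function(cl) {
    fa <- if (is.null(a[[cl]])) character(0) else a[[cl]]
    fb <- if (is.null(b[[cl]])) character(0) else b[[cl]]
    list(shared = sort(intersect(fa, fb)),
         only_a = sort(setdiff(fa, fb)),
         only_b = sort(setdiff(fb, fa)))
  })
  setNames(out, classes)
}
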