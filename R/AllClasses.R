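#' @import methods
NULL

## Allowed residue alphabet: 20 canonical one-letter codes plus X (unknown).
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_ALLOWED <- c(.AA_ALPHABET, "X")

#' ProteinSequence: a residue string with a parent-protein numbering offset
#'
#' Holds a one-letter amino acid string together with the 1-based position of
#' its first residue in the parent protein, so that peptides excised from a
#' full-length protein (for example a calmodulin-binding domain) keep their
#' native residue numbering. The i-th residue (1-based) sits at parent
#' position \code{offset + i - 1}.
#'
#' @slot id Sequence identifier (first FASTA header token).
#' @slot description Free-text description (remainder of the header).
#' @slot residues Uppercase one-letter amino acid string; the 20 canonical
#'   codes plus \code{X} are allowed. \code{X} never matches any anchor set
#'   or bracketed pattern class.
#' @slot offset 1-based parent-protein position of the first residue.
#'
#' @seealso [proteinSequence()], [readProteinFasta()], [extractRegion()]
#' @exportClass ProteinSequence
setClass("ProteinSequence",
  representation(
    id = "character",
    description = "character",
    residues = "character",
    offset = "integer"
  ),
  prototype(description = "", offset = 1L)
)

setValidity("ProteinSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@residues) != 1L || is.na(object@residues))
    msg <- c(msg, "'residues' must be a single string")
  else {
    if (nchar(object@residues) < 1L)
      msg <- c(msg, "sequence must contain at least one residue")
    ch <- strsplit(object@residues, "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% .AA_ALLOWED))
    if (length(bad))
      msg <- c(msg, sprintf("illegal residue '%s' at position %d",
                            ch[bad[1L]], bad[1L]))
  }
  if (length(object@offset) != 1L || is.na(object@offset) || object@offset < 1L)
    msg <- c(msg, "'offset' must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' SequenceRegion: a 1-based inclusive interval on a parent protein
#'
#' @slot parentId Identifier of the parent sequence.
#' @slot start,end 1-based inclusive bounds in parent-protein coordinates.
#'
#' @seealso [sequenceRegion()], [extractRegion()], [annotateOverlap()]
#' @exportClass SequenceRegion
setClass("SequenceRegion",
  representation(parentId = "character", start = "integer", end = "integer")
)

setValidity("SequenceRegion", function(object) {
  msg <- character()
  if (length(object@start) != 1L || length(object@end) != 1L ||
      is.na(object@start) || is.na(object@end))
    msg <- c(msg, "'start' and 'end' must be single integers")
  else {
    if (object@start < 1L) msg <- c(msg, "'start' must be >= 1")
    if (object@start > object@end)
      msg <- c(msg, sprintf("'start' (%d) must be <= 'end' (%d)",
                            object@start, object@end))
  }
  if (length(msg)) msg else TRUE
})

#' MotifClass: a named anchor-spacing pattern
#'
#' A canonical calmodulin-binding motif class is defined by the relative
#' positions of its required bulky hydrophobic anchor residues, counted
#' inclusively from the first anchor ("1-5-10" places anchors at relative
#' positions 1, 5 and 10, i.e. 0-based offsets 0, 4, 9). A three-anchor class
#' may refine a two-anchor parent sharing its terminal anchors (1-5-10
#' refines 1-10; 1-8-14 refines 1-14); curated reporting uses this to
#' suppress the less specific coterminal match.
#'
#' @slot name Class name, e.g. \code{"1-5-10"}.
#' @slot anchorOffsets Strictly increasing 0-based offsets from the first
#'   anchor; the first offset is always 0.
#' @slot parent Name of the two-anchor class this class refines, or
#'   \code{NA_character_}.
#'
#' @seealso [motifClasses()], [enumerateMatches()]
#' @exportClass MotifClass
setClass("MotifClass",
  representation(name = "character", anchorOffsets = "integer",
                 parent = "character"),
  prototype(parent = NA_character_)
)

setValidity("MotifClass", function(object) {
  msg <- character()
  off <- object@anchorOffsets
  if (length(off) < 2L)
    msg <- c(msg, "a motif class needs at least two anchors")
  else {
    if (off[1L] != 0L) msg <- c(msg, "first anchor offset must be 0")
    if (any(diff(off) <= 0L))
      msg <- c(msg, "anchor offsets must be strictly increasing")
    ## name encodes 1-based anchor positions within the motif
    expected <- paste(off + 1L, collapse = "-")
    if (!identical(object@name, expected))
      msg <- c(msg, sprintf("name '%s' does not encode offsets (expected '%s')",
                            object@name, expected))
  }
  if (length(msg)) msg else TRUE
})

#' AnchorSet: the residue letters accepted as hydrophobic anchors
#'
#' The core set holds the canonical anchor hydrophobics Phe, Ile, Leu, Val
#' and Trp; the extended set adds Met and Tyr, which some curated motif
#' fingerprints require.
#'
#' @slot name Set name ("core" or "extended" for the built-ins).
#' @slot letters Residue letters belonging to the set.
#'
#' @seealso [anchorSet()]
#' @exportClass AnchorSet
setClass("AnchorSet",
  representation(name = "character", letters = "character")
)

setValidity("AnchorSet", function(object) {
  msg <- character()
  if (length(object@letters) < 1L)
    msg <- c(msg, "anchor set must be non-empty")
  if (!all(object@letters %in% .AA_ALPHABET))
    msg <- c(msg, "anchor letters must be canonical amino acid codes")
  if (anyDuplicated(object@letters))
    msg <- c(msg, "anchor letters must be unique")
  if (length(msg)) msg else TRUE
})

#' ResidueScoreProfile: per-residue CaMBD propensity scores
#'
#' One score in [0, 9] per residue of the scanned sequence, computed by
#' [residueScores()] from windowed hydropathy, net positive charge and helix
#' propensity. The offset maps profile indices back to parent-protein
#' coordinates.
#'
#' @slot parentId Identifier of the scored sequence.
#' @slot offset 1-based parent position of the first profiled residue.
#' @slot scores Numeric vector of combined scores, all within [0, 9].
#' @slot window Nominal (odd) window width used.
#'
#' @seealso [residueScores()], [callCandidates()]
#' @exportClass ResidueScoreProfile
setClass("ResidueScoreProfile",
  representation(parentId = "character", offset = "integer",
                 scores = "numeric", window = "integer")
)

setValidity("ResidueScoreProfile", function(object) {
  msg <- character()
  if (length(object@scores) < 1L)
    msg <- c(msg, "profile must cover at least one residue")
  if (any(object@scores < -1e-9 | object@scores > 9 + 1e-9))
    msg <- c(msg, "all scores must lie within [0, 9]")
  if (length(msg)) msg else TRUE
})

#' ScoringWeights: mixture weights for the CaMBD propensity score
#'
#' Non-negative weights for the hydropathy, net-positive-charge and helix
#' propensity components; they must sum to 1.
#'
#' @slot hydropathy,charge,helix Component weights.
#'
#' @seealso [scoringWeights()], [residueScores()]
#' @exportClass ScoringWeights
setClass("ScoringWeights",
  representation(hydropathy = "numeric", charge = "numeric", helix = "numeric")
)

setValidity("ScoringWeights", function(object) {
  w <- c(object@hydropathy, object@charge, object@helix)
  msg <- character()
  if (any(w < 0)) msg <- c(msg, "weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SiteTable: curated Tau phosphorylation/dephosphorylation sites
#'
#' Transcribed site-level records (2N4R numbering, 441 residues) of which
#' kinase phosphorylates or which phosphatase dephosphorylates each Tau
#' residue, with reported effect sizes where available, plus per-enzyme
#' potential-site counts and transcription provenance used for integrity
#' checks.
#'
#' @slot sites data.frame with columns position, residue, enzyme, direction,
#'   effect_pct, stage, citation, note.
#' @slot counts data.frame of per-enzyme potential phosphosite counts.
#' @slot provenance data.frame of expected transcribed row counts per enzyme
#'   and isoform-level totals.
#'
#' @seealso [loadSiteTable()], [annotateOverlap()], [lookupSites()]
#' @exportClass SiteTable
setClass("SiteTable",
  representation(sites = "data.frame", counts = "data.frame",
                 provenance = "data.frame")
)

setValidity("SiteTable", function(object) {
  s <- object@sites
  msg <- character()
  need <- c("position", "residue", "enzyme", "direction", "effect_pct",
            "stage", "citation")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("sites table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (!all(s$residue %in% c("S", "T", "Y")))
      msg <- c(msg, "site residues must be S, T or Y")
    if (!all(s$direction %in% c("phosphorylates", "dephosphorylates")))
      msg <- c(msg, "direction must be phosphorylates or dephosphorylates")
    ok <- is.na(s$effect_pct) | (s$effect_pct > 0 & s$effect_pct <= 100)
    if (!all(ok)) msg <- c(msg, "effect_pct must lie in (0, 100]")
    if (anyDuplicated(s[, c("position", "enzyme", "direction")]))
      msg <- c(msg, "duplicate (position, enzyme, direction) triple")
  }
  if (length(msg)) msg else TRUE
})

#' Fixture: a packaged CaMBD peptide with its curated annotation
#'
#' @slot name Fixture name.
#' @slot sequence The packaged [ProteinSequence-class] peptide.
#' @slot printedStart Start label as originally printed (may differ from the
#'   canonical offset used by the sequence; see the Tau R2 fixture).
#' @slot printedClasses Motif classes reported for the peptide.
#' @slot printedCount Reported motif count, or NA.
#' @slot status One of "clean", "label-inconsistent", "curation-ambiguous".
#'   A fixture is clean exactly when the curated exhaustive scan with core
#'   anchors reproduces the reported count and classes.
#' @slot note Free-text caveats (typos, offset discrepancies).
#'
#' @seealso [fixtureLibrary()], [fixtureTable()]
#' @exportClass Fixture
setClass("Fixture",
  representation(name = "character", sequence = "ProteinSequence",
                 printedStart = "integer", printedClasses = "character",
                 printedCount = "integer", status = "character",
                 note = "character")
)

setValidity("Fixture", function(object) {
  if (!object@status %in% c("clean", "label-inconsistent",
                            "curation-ambiguous"))
    return("unknown fixture status")
  TRUE
})

#' ScanReport: a serializable container for one scan run
#'
#' Bundles the matches of a motif scan with the settings that produced them
#' so results round-trip losslessly through JSON and TSV.
#'
#' @slot version Package version string.
#' @slot input Description of the scanned input (e.g. a FASTA path).
#' @slot mode "raw" or "curated".
#' @slot anchors Anchor set name used.
#' @slot matches Match table as returned by [scanMotifs()].
#'
#' @seealso [scanReport()], [writeScanReport()], [readScanReport()]
#' @exportClass ScanReport
setClass("ScanReport",
  representation(version = "character", input = "character",
                 mode = "character", anchors = "character",
                 matches = "DataFrame")
)

setValidity("ScanReport", function(object) {
  if (!object@mode %in% c("raw", "curated"))
    return("mode must be 'raw' or 'curated'")
  TRUE
})
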