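setMethod("show", "Fixture", function(object) {
  cat(sprintf("Fixture '%s' [%s]: %d aa at %d-%d\n", object@name,
              object@status, length(object@sequence),
              seqOffset(object@sequence), seqEnd(object@sequence)))
  cat(sprintf("  reported motifs: %s (count %s)\n",
              paste(object@printedClasses, collapse = ", "),
              object@printedCount))
  if (!is.na(object@note) && nzchar(object@note))
    cat("  note:", object@note, "\n")
})

#' Annotation sidecar for the packaged CaMBD fixtures
#'
#' One row per curated calmodulin-binding domain peptide reported for Tau
#' and its calmodulin-regulated kinases/phosphatase, including the one
#' (MARK4) whose sequence is not packaged because it is available only as
#' a figure image.
#'
#' @return A data.frame with columns name, packaged, printed_start,
#'   printed_classes, printed_count, status, note.
#' @seealso [fixtureLibrary()]
#' @export
fixtureTable <- function() {
  path <- system.file("extdata", "cambd_fixtures.tsv", package = "CaMScan",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' The packaged CaMBD fixture library
#'
#' Loads the curated calmodulin-binding domain peptides with their
#' annotations. Each fixture's status records whether the curated
#' exhaustive motif scan (core anchors) reproduces the reported motif
#' count and classes exactly ("clean"), or whether the reported annotation
#' is internally inconsistent ("label-inconsistent") or not reproducible
#' by exhaustive scanning ("curation-ambiguous"); only clean fixtures feed
#' count-based tests.
#'
#' @return A named list of [Fixture-class] objects (packaged fixtures
#'   only).
#' @examples
#' fx <- fixtureLibrary()
#' fx[["CaMKIIA"]]
#' scanMotifs(fx[["CaMKIIA"]]@sequence)
#' @export
fixtureLibrary <- function() {
  meta <- fixtureTable()
  fasta <- system.file("extdata", "cambd_fixtures.fasta",
                       package = "CaMScan", mustWork = TRUE)
  seqs <- readProteinFasta(fasta)
  meta <- meta[meta$packaged, , drop = FALSE]
  out <- lapply(seq_len(nrow(meta)), function(i) {
    nm <- meta$name[i]
    if (is.null(seqs[[nm]]))
      stop("fixture sequence missing from FASTA: ", nm)
    new("Fixture", name = nm, sequence = seqs[[nm]],
        printedStart = as.integer(meta$printed_start[i]),
        printedClasses = strsplit(meta$printed_classes[i], ",",
                                  fixed = TRUE)[[1L]],
        printedCount = as.integer(meta$printed_count[i]),
        status = meta$status[i],
        note = as.character(meta$note[i]))
  })
  names(out) <- meta$name
  out
}

## background alphabet free of core anchors (F,I,L,V,W) and charge (R,K,D,E
## retained except basics): exclude anchors and R/K so embedded signals have
## a zero false-positive floor
.BG_ALPHABET <- setdiff(.AA_ALPHABET,
                        c("F", "I", "L", "V", "W", "R", "K"))

## run code under a fixed RNG seed without disturbing the caller's stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic protein with an optional embedded segment
#'
#' Draws a background sequence and optionally splices in a given segment
#' (e.g. a basic amphipathic 20-mer) at a fixed or seeded-random position.
#' In the default mode the background alphabet excludes the core anchor
#' residues (F, I, L, V, W) and the basic residues R and K, so motif and
#' predictor tests on embedded signals have a zero false-positive floor;
#' `realistic = TRUE` instead draws uniformly from all 20 residues for
#' stress tests. Output is deterministic for a fixed seed and does not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer RNG seed.
#' @param bgLen Background length (the final sequence keeps this length;
#'   the embedded segment replaces background residues).
#' @param embed Optional residue string to splice in.
#' @param embedPos Optional 1-based splice position; random when NULL.
#' @param realistic Draw background uniformly from all 20 residues.
#' @return A [ProteinSequence-class] with offset 1; when a segment is
#'   embedded, its location is recorded in the description as
#'   \code{embed_start=<i> embed_end=<j>}.
#' @examples
#' synthProtein(42, 400, embed = "KLWKKLLKLFSKLWKQIKKV")
#' @export
synthProtein <- function(seed, bgLen, embed = NULL, embedPos = NULL,
                         realistic = FALSE) {
  bgLen <- as.integer(bgLen)
  stopifnot(bgLen >= 1L)
  alpha <- if (realistic) .AA_ALPHABET else .BG_ALPHABET
  .withSeed(seed, {
    ch <- sample(alpha, bgLen, replace = TRUE)
    desc <- ""
    if (!is.null(embed)) {
      embed <- toupper(embed)
      eLen <- nchar(embed)
      if (eLen > bgLen)
        stop(sprintf("embedded segment (%d aa) longer than background (%d)",
                     eLen, bgLen))
      if (is.null(embedPos))
        embedPos <- sample.int(bgLen - eLen + 1L, 1L)
      embedPos <- as.integer(embedPos)
      if (embedPos < 1L || embedPos + eLen - 1L > bgLen)
        stop("'embedPos' places the segment out of bounds")
      ch[embedPos:(embedPos + eLen - 1L)] <-
        strsplit(embed, "", fixed = TRUE)[[1L]]
      desc <- sprintf("embed_start=%d embed_end=%d", embedPos,
                      embedPos + eLen - 1L)
    }
    proteinSequence(sprintf("synth-seed%d", seed),
                    paste(ch, collapse = ""), offset = 1L,
                    description = desc)
  })
}

#' Embedded-segment coordinates of a synthetic protein
#'
#' @param seq A [ProteinSequence-class] produced by [synthProtein()] with
#'   an embedded segment.
#' @return Integer vector c(start, end), or NULL if nothing was embedded.
#' @export
embeddedSpan <- function(seq) {
  m <- regmatches(seq@description,
                  regexec("embed_start=(\\d+) embed_end=(\\d+)",
                          seq@description))[[1L]]
  if (length(m) == 0L) return(NULL)
  as.integer(m[2:3])
}
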