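#' Convert a match table to a plain data.frame
#'
#' Anchor positions are comma-joined into a single column, giving the
#' layout used for TSV and JSON serialization: seq_id, class_name,
#' anchor_positions, fingerprint, span_start, span_end.
#'
#' @param matches A match table from [scanMotifs()].
#' @return A plain data.frame.
#' @seealso [matchesFromDataFrame()]
#' @export
matchesAsDataFrame <- function(matches) {
  data.frame(
    seq_id = as.character(matches$seq_id),
    class_name = as.character(matches$class_name),
    anchor_positions = vapply(as.list(matches$anchor_positions),
                              paste, character(1L), collapse = ","),
    fingerprint = as.character(matches$fingerprint),
    span_start = as.integer(matches$span_start),
    span_end = as.integer(matches$span_end),
    stringsAsFactors = FALSE)
}

#' Rebuild a match table from its serialized data.frame form
#'
#' @param df A data.frame as produced by [matchesAsDataFrame()].
#' @return A `DataFrame` match table equal to the original.
#' @export
matchesFromDataFrame <- function(df) {
  if (nrow(df) == 0L) return(.emptyMatches())
  S4Vectors::DataFrame(
    seq_id = as.character(df$seq_id),
    class_name = as.character(df$class_name),
    anchor_positions = IRanges::IntegerList(
      lapply(strsplit(as.character(df$anchor_positions), ",", fixed = TRUE),
             as.integer)),
    fingerprint = as.character(df$fingerprint),
    span_start = as.integer(df$span_start),
    span_end = as.integer(df$span_end))
}

#' Bundle scan results into a ScanReport
#'
#' @param matches A match table from [scanMotifs()].
#' @param input Description of the scanned input (e.g. a FASTA path).
#' @param mode "raw" or "curated".
#' @param anchors Anchor set name used.
#' @return A [ScanReport-class] object.
#' @export
scanReport <- function(matches, input = "", mode = "curated",
                       anchors = "core") {
  new("ScanReport",
      version = as.character(utils::packageVersion("CaMScan")),
      input = input, mode = mode, anchors = anchors, matches = matches)
}

setMethod("show", "ScanReport", function(object) {
  cat(sprintf("ScanReport (CaMScan %s): %d %s-mode matches (%s anchors)\n",
              object@version, nrow(object@matches), object@mode,
              object@anchors))
})

#' Convert motif spans to BED intervals
#'
#' BED uses 0-based half-open coordinates, so a 1-based inclusive span
#' (start, end) becomes (start - 1, end).
#'
#' @param matches A match table from [scanMotifs()].
#' @return A data.frame with columns chrom, chromStart, chromEnd, name,
#'   score, strand.
#' @export
matchesToBED <- function(matches) {
  data.frame(
    chrom = as.character(matches$seq_id),
    chromStart = as.integer(matches$span_start) - 1L,
    chromEnd = as.integer(matches$span_end),
    name = as.character(matches$class_name),
    score = 0L,
    strand = ".",
    stringsAsFactors = FALSE)
}

#' Write a ScanReport to TSV, JSON or BED
#'
#' TSV holds one row per match (header always written, so an empty scan
#' yields a header-only file); JSON is lossless and round-trips through
#' [readScanReport()]; BED converts spans to 0-based half-open intervals.
#'
#' @param report A [ScanReport-class].
#' @param path Output path.
#' @param format One of "tsv", "json", "bed".
#' @return Invisibly, `path`.
#' @export
writeScanReport <- function(report, path, format = c("tsv", "json", "bed")) {
  stopifnot(is(report, "ScanReport"))
  format <- match.arg(format)
  df <- matchesAsDataFrame(report@matches)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "bed") {
    utils::write.table(matchesToBED(report@matches), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    payload <- list(version = report@version, input = report@input,
                    mode = report@mode, anchors = report@anchors,
                    matches = df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read a ScanReport back from JSON or TSV
#'
#' JSON restores the full report; TSV restores the match table with
#' default metadata.
#'
#' @param path Input path.
#' @param format "json" (default) or "tsv".
#' @return A [ScanReport-class].
#' @export
readScanReport <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(anchor_positions = "character"))
    return(scanReport(matchesFromDataFrame(df), input = path))
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- payload$matches
  if (is.null(df) || length(df) == 0L)
    df <- matchesAsDataFrame(.emptyMatches())
  rep <- scanReport(matchesFromDataFrame(df), input = payload$input,
                    mode = payload$mode, anchors = payload$anchors)
  rep@version <- payload$version
  rep
}
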