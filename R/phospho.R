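#' Load the packaged Tau phosphosite table
#'
#' Returns the curated table of Tau (2N4R numbering, 441 residues)
#' phosphorylation and dephosphorylation sites transcribed from the
#' literature: CaMKII and Cdk5 kinase targets, GSK3beta hyperphosphorylation
#' sites, the MARK4 site, calcineurin (CN) dephosphorylation sites with
#' reported percent decreases in phosphorylation, and the two AD-associated
#' serines inside the Tau calmodulin-binding domain. Also carries
#' per-kinase potential-site counts (85 potential sites in total: 45 Ser,
#' 35 Thr, 5 Tyr) and transcription provenance used for integrity checks.
#'
#' @return A [SiteTable-class] object.
#' @examples
#' tab <- loadSiteTable()
#' lookupSites(tab, enzyme = "CN", position = 396)$effect_pct  # 78
#' @export
loadSiteTable <- function() {
  ext <- function(f) system.file("extdata", f, package = "CaMScan",
                                 mustWork = TRUE)
  sites <- utils::read.delim(ext("tau_phospho_sites.tsv"),
                             stringsAsFactors = FALSE, na.strings = "NA")
  if (!"note" %in% names(sites)) sites$note <- NA_character_
  sites$effect_pct <- as.numeric(sites$effect_pct)
  sites <- sites[order(sites$position, sites$enzyme), , drop = FALSE]
  rownames(sites) <- NULL
  counts <- utils::read.delim(ext("tau_site_counts.tsv"),
                              stringsAsFactors = FALSE)
  prov <- utils::read.delim(ext("tau_phospho_provenance.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  new("SiteTable", sites = sites, counts = counts, provenance = prov)
}

setMethod("show", "SiteTable", function(object) {
  cat(sprintf(
    "SiteTable: %d transcribed Tau sites (2N4R numbering), %d enzymes\n",
    nrow(object@sites), length(unique(object@sites$enzyme))))
  cat(sprintf("  potential phosphosite counts for %d kinases attached\n",
              nrow(object@counts)))
})

#' Query phosphosite records by enzyme and/or position
#'
#' @param table A [SiteTable-class].
#' @param enzyme Optional enzyme name; an unknown enzyme yields zero rows,
#'   not an error.
#' @param position Optional 2N4R residue position.
#' @return A data.frame of matching site records.
#' @export
lookupSites <- function(table, enzyme = NULL, position = NULL) {
  stopifnot(is(table, "SiteTable"))
  s <- table@sites
  if (!is.null(enzyme)) s <- s[s$enzyme == enzyme, , drop = FALSE]
  if (!is.null(position)) s <- s[s$position == position, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Potential phosphosite count metadata per kinase
#'
#' @param table A [SiteTable-class].
#' @param enzyme Optional enzyme name; when given, returns its potential
#'   site count as an integer (NA if the enzyme has no count record).
#' @return The counts data.frame, or a single integer when `enzyme` is
#'   given.
#' @examples
#' siteCounts(loadSiteTable(), "MARK4")  # 2
#' @export
siteCounts <- function(table, enzyme = NULL) {
  stopifnot(is(table, "SiteTable"))
  if (is.null(enzyme)) return(table@counts)
  hit <- table@counts$n_sites[table@counts$enzyme == enzyme]
  if (length(hit) == 0L) NA_integer_ else as.integer(hit[1L])
}

#' Sites overlapping a scanned region
#'
#' Returns every transcribed site whose 2N4R position falls inside the
#' region (inclusive bounds), sorted by position — e.g. the Tau
#' calmodulin-binding domain region 287-304 contains the AD-phosphorylated
#' Ser289 and Ser293.
#'
#' @param region A [SequenceRegion-class] in 2N4R coordinates.
#' @param table A [SiteTable-class] (default: the packaged table).
#' @return A data.frame of site records inside the region.
#' @examples
#' annotateOverlap(sequenceRegion("Tau", 287, 304))
#' @export
annotateOverlap <- function(region, table = loadSiteTable()) {
  stopifnot(is(region, "SequenceRegion"), is(table, "SiteTable"))
  s <- table@sites
  s <- s[s$position >= region@start & s$position <= region@end, ,
         drop = FALSE]
  s <- s[order(s$position, s$enzyme), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Export the phosphosite table as TSV
#'
#' Writes the columns position, residue, enzyme, direction, effect_pct,
#' stage, citation.
#'
#' @param table A [SiteTable-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
exportSiteTable <- function(table, path) {
  stopifnot(is(table, "SiteTable"))
  cols <- c("position", "residue", "enzyme", "direction", "effect_pct",
            "stage", "citation")
  utils::write.table(table@sites[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
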