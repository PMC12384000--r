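## Independent brute-force oracles, deliberately written with naive
## per-position loops on plain strings so they share no code path with the
## package's vectorized scanners.

## every (class, start) pair tested independently; returns a data.frame
## with one row per raw match in (span_start, span, class) order
bruteForceEnumerate <- function(residueString, offset = 1L,
                                classOffsets = list(
                                  "1-10" = c(0, 9), "1-12" = c(0, 11),
                                  "1-14" = c(0, 13), "1-16" = c(0, 15),
                                  "1-5-10" = c(0, 4, 9),
                                  "1-8-13" = c(0, 7, 12),
                                  "1-8-14" = c(0, 7, 13)),
                                anchorLetters = c("F", "I", "L", "V", "W")) {
  n <- nchar(residueString)
  rows <- list()
  for (cn in names(classOffsets)) {
    off <- classOffsets[[cn]]
    for (s in seq_len(n)) {
      if (s + max(off) > n) next
      hit <- TRUE
      fp <- ""
      for (o in off) {
        aa <- substr(residueString, s + o, s + o)
        if (!aa %in% anchorLetters) { hit <- FALSE; break }
        fp <- paste0(fp, aa)
      }
      if (hit)
        rows[[length(rows) + 1L]] <- data.frame(
          class_name = cn,
          anchors = paste(offset + s - 1L + off, collapse = ","),
          fingerprint = fp,
          span_start = offset + s - 1L,
          span_end = offset + s - 1L + max(off),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(class_name = character(0), anchors = character(0),
                      fingerprint = character(0), span_start = integer(0),
                      span_end = integer(0)))
  df <- do.call(rbind, rows)
  span <- df$span_end - df$span_start + 1L
  df <- df[order(df$span_start, span, df$class_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## character-by-character IQ check of every 14-residue window
iqOracle <- function(residueString) {
  n <- nchar(residueString)
  cls <- list(`1` = c("F", "I", "L", "V"), `2` = "Q", `6` = c("R", "K"),
              `7` = "G", `11` = c("R", "K"),
              `14` = c("F", "I", "L", "V", "W", "Y"))
  starts <- integer(0)
  for (s in seq_len(max(0L, n - 13L))) {
    ok <- TRUE
    for (p in names(cls)) {
      aa <- substr(residueString, s + as.integer(p) - 1L,
                   s + as.integer(p) - 1L)
      if (!aa %in% cls[[p]]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

## per-position profile oracle: explicit loop over truncated windows
profileOracle <- function(residueString, wH, wC, wX, window = 21L,
                          histidineCharge = 0) {
  kd <- hydropathyScale()
  cf <- helixPropensityScale()
  ch <- strsplit(residueString, "")[[1]]
  n <- length(ch)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- ch[max(1L, i - h):min(n, i + h)]
    m <- length(win)
    kdv <- ifelse(win %in% names(kd), kd[win], min(kd))
    hyd <- (mean(kdv) - min(kd)) / (max(kd) - min(kd))
    cfv <- ifelse(win %in% names(cf), cf[win], min(cf))
    hel <- (mean(cfv) - min(cf)) / (max(cf) - min(cf))
    q <- sum(win %in% c("R", "K")) - sum(win %in% c("D", "E")) +
      histidineCharge * sum(win == "H")
    chg <- min(max(q / m, 0), 1)
    out[i] <- 9 * (wH * hyd + wC * chg + wX * hel)
  }
  out
}

## flatten a match table for easy comparison with the brute-force oracle
matchKey <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(m$class_name,
        vapply(as.list(m$anchor_positions), paste, "", collapse = ","),
        m$fingerprint, m$span_start, m$span_end)
}

## Jaccard overlap of two inclusive integer intervals
jaccardSpan <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  union <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / union
}

## random residue string over a given alphabet
randomResidues <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
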