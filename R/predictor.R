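## Kyte-Doolittle hydropathy index (Kyte & Doolittle 1982, J Mol Biol 157).
.KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

## Chou-Fasman alpha-helix propensity P(a) (Chou & Fasman 1978).
.CF_HELIX <- c(
  E = 1.51, M = 1.45, A = 1.42, L = 1.21, K = 1.16, F = 1.13, Q = 1.11,
  W = 1.08, I = 1.08, V = 1.06, D = 1.01, H = 1.00, R = 0.98, T = 0.83,
  S = 0.77, C = 0.70, Y = 0.69, N = 0.67, P = 0.57, G = 0.57)

#' Residue property scales used by the CaMBD propensity score
#'
#' `hydropathyScale()` returns the Kyte-Doolittle hydropathy index;
#' `helixPropensityScale()` the Chou-Fasman alpha-helix propensity.
#' Residues absent from a scale (i.e. \code{X}) score the scale minimum.
#'
#' @return A named numeric vector over the 20 canonical residues.
#' @name propensity-scales
NULL

#' @rdname propensity-scales
#' @export
hydropathyScale <- function() .KD_HYDROPATHY

#' @rdname propensity-scales
#' @export
helixPropensityScale <- function() .CF_HELIX

#' Construct scoring weights for the CaMBD propensity score
#'
#' @param hydropathy,charge,helix Non-negative weights for the mean
#'   hydropathy, net positive charge and mean helix propensity components;
#'   must sum to 1. The defaults weight hydrophobicity and basicity equally
#'   — the two properties that jointly define a basic amphipathic
#'   calmodulin-binding helix — with helix propensity as a lighter tiebreak.
#' @return A [ScoringWeights-class] object.
#' @export
scoringWeights <- function(hydropathy = 0.4, charge = 0.4, helix = 0.2) {
  new("ScoringWeights", hydropathy = as.numeric(hydropathy),
      charge = as.numeric(charge), helix = as.numeric(helix))
}

setMethod("show", "ScoringWeights", function(object) {
  cat(sprintf("ScoringWeights: hydropathy %.2f, charge %.2f, helix %.2f\n",
              object@hydropathy, object@charge, object@helix))
})

setMethod("show", "ResidueScoreProfile", function(object) {
  cat(sprintf(
    "ResidueScoreProfile '%s': %d residues (positions %d-%d), window %d\n",
    object@parentId, length(object@scores), object@offset,
    object@offset + length(object@scores) - 1L, object@window))
  cat(sprintf("  score range %.2f-%.2f (scale 0-9)\n",
              min(object@scores), max(object@scores)))
})

## windowed mean of v with truncated edge windows, half-width h
.windowMean <- function(v, h) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-residue calmodulin-binding propensity profile
#'
#' For each residue, over a centered window (truncated at the ends of the
#' sequence), combines three normalized components: (a) mean Kyte-Doolittle
#' hydropathy, min-max scaled to [0, 1] over the scale range; (b) net
#' positive charge fraction, \code{(count(R,K) - count(D,E)) / window
#' length}, clipped to [0, 1]; (c) mean Chou-Fasman helix propensity,
#' min-max scaled over its range. The weighted sum is rescaled to [0, 9].
#' This is a documented heuristic for proposing basic amphipathic candidate
#' CaMBDs; it does not reproduce any external database's scoring.
#'
#' @param seq A [ProteinSequence-class] at least as long as `window`.
#' @param weights A [ScoringWeights-class] (default [scoringWeights()]).
#' @param window Odd window width (default 21).
#' @param histidineCharge Charge assigned to His (default 0; set 0.5 to
#'   count it half-protonated).
#' @return A [ResidueScoreProfile-class].
#' @seealso [callCandidates()], [predictCaMBD()]
#' @export
residueScores <- function(seq, weights = scoringWeights(), window = 21L,
                          histidineCharge = 0) {
  stopifnot(is(seq, "ProteinSequence"), is(weights, "ScoringWeights"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  n <- nchar(seq@residues)
  if (n < window)
    stop(sprintf(paste0("sequence '%s' (%d aa) is shorter than the window ",
                        "(%d); scan it for motifs directly instead"),
                 seq@id, n, window))
  ch <- .residueVector(seq)
  h <- (window - 1L) %/% 2L

  kd <- .KD_HYDROPATHY[ch]
  kd[is.na(kd)] <- min(.KD_HYDROPATHY)
  hyd <- (.windowMean(kd, h) - min(.KD_HYDROPATHY)) /
    diff(range(.KD_HYDROPATHY))

  cf <- .CF_HELIX[ch]
  cf[is.na(cf)] <- min(.CF_HELIX)
  hel <- (.windowMean(cf, h) - min(.CF_HELIX)) / diff(range(.CF_HELIX))

  chg <- numeric(n)
  chg[ch %in% c("R", "K")] <- 1
  chg[ch %in% c("D", "E")] <- -1
  chg[ch == "H"] <- histidineCharge
  charge <- pmin(pmax(.windowMean(chg, h), 0), 1)

  combined <- 9 * (weights@hydropathy * hyd + weights@charge * charge +
                   weights@helix * hel)
  new("ResidueScoreProfile", parentId = seq@id, offset = seq@offset,
      scores = as.numeric(combined), window = window)
}

## best-sum window of length len whose start index lies in [sMin, sMax]
.bestWindow <- function(cs, len, sMin, sMax) {
  starts <- sMin:sMax
  sums <- cs[starts + len] - cs[starts]
  s <- starts[which.max(sums)]   # which.max is leftmost on ties
  list(start = s, sum = max(sums))
}

#' Call candidate calmodulin-binding domains from a propensity profile
#'
#' Maximal runs of positions scoring at least `threshold` are shaped into
#' candidate windows of 18-22 residues: runs already inside the length
#' bounds are kept as-is; longer runs are trimmed to the maximum-score
#' sub-window of `maxLen` residues; shorter runs are extended to the
#' maximum-score containing window of `minLen` residues (ties resolved
#' leftmost). Overlapping candidates are resolved by keeping the
#' higher-scoring one (leftmost on ties); survivors are ranked by
#' descending score.
#'
#' @param profile A [ResidueScoreProfile-class].
#' @param threshold Score threshold in [0, 9]. The default 3.5 separates
#'   basic amphipathic segments (which plateau near 4-4.5 under this
#'   normalization, since the mean hydropathy of a charged amphipathic
#'   helix sits near the scale midpoint, not its maximum) from uniform
#'   background (about 2, never observed above 3 in anchor-free synthetic
#'   background).
#' @param minLen,maxLen Candidate length bounds (defaults 18 and 22).
#' @return A data.frame with columns seq_id, start, end, length, score
#'   (mean profile score over the window) and rank, in parent coordinates,
#'   ordered by rank; zero rows when nothing exceeds the threshold.
#' @export
callCandidates <- function(profile, threshold = 3.5, minLen = 18L,
                           maxLen = 22L) {
  stopifnot(is(profile, "ResidueScoreProfile"))
  if (threshold < 0 || threshold > 9) stop("'threshold' must be in [0, 9]")
  minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
  stopifnot(minLen >= 1L, minLen <= maxLen)
  sc <- profile@scores
  n <- length(sc)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      score = numeric(0), rank = integer(0))
  r <- rle(sc >= threshold)
  if (!any(r$values)) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  cs <- c(0, cumsum(sc))

  cand <- list()
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    len <- b - a + 1L
    if (len < minLen) {
      if (n < minLen) next  # sequence cannot host a minimum-length window
      sMin <- max(1L, b - minLen + 1L)
      sMax <- min(a, n - minLen + 1L)
      if (sMin > sMax) next
      w <- .bestWindow(cs, minLen, sMin, sMax)
      a <- w$start; b <- w$start + minLen - 1L
    } else if (len > maxLen) {
      w <- .bestWindow(cs, maxLen, a, b - maxLen + 1L)
      a <- w$start; b <- w$start + maxLen - 1L
    }
    cand[[length(cand) + 1L]] <-
      c(start = a, end = b, score = mean(sc[a:b]))
  }
  if (length(cand) == 0L) return(empty)
  df <- as.data.frame(do.call(rbind, cand))
  ## resolve overlaps greedily: higher score wins, leftmost on ties
  ord <- order(-df$score, df$start)
  keep <- logical(nrow(df))
  occupied <- logical(n)
  for (i in ord) {
    span <- df$start[i]:df$end[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  df <- df[keep, , drop = FALSE]
  ord <- order(-df$score, df$start)
  df <- df[ord, , drop = FALSE]
  data.frame(seq_id = profile@parentId,
             start = profile@offset + as.integer(df$start) - 1L,
             end = profile@offset + as.integer(df$end) - 1L,
             length = as.integer(df$end - df$start + 1L),
             score = df$score,
             rank = seq_len(nrow(df)),
             row.names = NULL)
}

#' Predict candidate calmodulin-binding domains in a protein
#'
#' Convenience wrapper around [residueScores()] and [callCandidates()].
#'
#' @inheritParams residueScores
#' @inheritParams callCandidates
#' @return A candidate data.frame; see [callCandidates()].
#' @examples
#' s <- synthProtein(42, 400, embed = "KLWKKLLKLFSKLWKQIKKV")
#' predictCaMBD(s)
#' @export
predictCaMBD <- function(seq, weights = scoringWeights(), window = 21L,
                         threshold = 3.5, minLen = 18L, maxLen = 22L,
                         histidineCharge = 0) {
  callCandidates(residueScores(seq, weights, window, histidineCharge),
                 threshold = threshold, minLen = minLen, maxLen = maxLen)
}
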