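test_that("profiles match a per-window oracle and stay within [0, 9]", {
  withr::local_seed(21)
  for (rep in 1:10) {
    res <- randomResidues(sample(25:120, 1),
                          c(LETTERS[LETTERS %in% c("A", "C", "D", "E", "F",
                                                   "G", "H", "I", "K", "L",
                                                   "M", "N", "P", "Q", "R",
                                                   "S", "T", "V", "W", "Y")],
                            "X"))
    w <- c(0.4, 0.4, 0.2)
    p <- residueScores(proteinSequence("p", res),
                       scoringWeights(w[1], w[2], w[3]))
    expect_equal(p@scores, profileOracle(res, w[1], w[2], w[3]),
                 tolerance = 1e-12)
    expect_true(all(p@scores >= 0 & p@scores <= 9))
  }
})

test_that("homopolymers give constant profiles with closed-form charge", {
  g <- residueScores(proteinSequence("g", strrep("G", 60)))
  expect_equal(length(unique(round(g@scores[11:50], 12))), 1L)
  # all-K vs all-G: charge component 1 vs 0 at interior positions
  onlyCharge <- scoringWeights(0, 1, 0)
  k <- residueScores(proteinSequence("k", strrep("K", 60)), onlyCharge)
  g2 <- residueScores(proteinSequence("g", strrep("G", 60)), onlyCharge)
  expect_equal(unique(k@scores), 9)
  expect_equal(unique(g2@scores), 0)
})

test_that("profile maximum falls inside an embedded amphipathic block", {
  block <- "KLWKKLLKLFSKLWKQIKKV"
  res <- paste0(strrep("G", 50), block, strrep("G", 50))
  p <- residueScores(proteinSequence("p", res),
                     scoringWeights(0.4, 0.4, 0.2), window = 21)
  peak <- which.max(p@scores)
  expect_true(peak >= 51 && peak <= 70)
})

test_that("components are monotone under hydrophobic and basic substitution", {
  # Ile sits above Gly on the hydropathy index (note Trp does not: the
  # index scores it mildly hydrophilic), and Lys adds positive charge
  base <- strrep("G", 41)
  hydOnly <- scoringWeights(1, 0, 0)
  chgOnly <- scoringWeights(0, 1, 0)
  for (i in c(1L, 10L, 21L, 35L)) {
    mutI <- base; substr(mutI, i, i) <- "I"
    mutK <- base; substr(mutK, i, i) <- "K"
    expect_true(all(
      residueScores(proteinSequence("i", mutI), hydOnly)@scores >=
        residueScores(proteinSequence("g", base), hydOnly)@scores - 1e-12))
    expect_true(all(
      residueScores(proteinSequence("k", mutK), chgOnly)@scores >=
        residueScores(proteinSequence("g", base), chgOnly)@scores - 1e-12))
  }
})

test_that("sequences shorter than the window are rejected with advice", {
  expect_error(residueScores(proteinSequence("s", "ACDEFGHIK")),
               "motif")
})

test_that("candidate calling shapes runs into 18-22 residue windows", {
  mkProfile <- function(scores, offset = 1L)
    new("ResidueScoreProfile", parentId = "p", offset = as.integer(offset),
        scores = scores, window = 21L)

  # constant zero profile: nothing called
  expect_equal(nrow(callCandidates(mkProfile(rep(0, 100)), threshold = 5)),
               0L)

  # a single 20-long supra-threshold run is returned as-is
  sc <- rep(1, 100); sc[41:60] <- 6
  out <- callCandidates(mkProfile(sc), threshold = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end, out$length), c(41, 60, 20))
  expect_equal(out$score, 6)
  expect_equal(out$rank, 1L)

  # long runs are trimmed to the best-scoring 22-mer
  sc <- rep(1, 100); sc[31:70] <- 6; sc[45:50] <- 8
  out <- callCandidates(mkProfile(sc), threshold = 5)
  expect_equal(out$length, 22L)
  expect_true(out$start <= 45 && out$end >= 50)

  # short runs are extended to 18, leftmost best window on flat scores
  sc <- rep(1, 100); sc[50:54] <- 7
  out <- callCandidates(mkProfile(sc), threshold = 5)
  expect_equal(out$length, 18L)
  expect_true(out$start <= 50 && out$end >= 54)

  # overlap resolution: two short runs whose 18-mer extensions collide;
  # the window around the score-7 run wins, the other is dropped
  sc <- rep(0, 60); sc[20:29] <- 5; sc[31:40] <- 7
  out <- callCandidates(mkProfile(sc), threshold = 4, minLen = 18,
                        maxLen = 22)
  expect_equal(nrow(out), 1L)
  expect_true(out$start <= 31 && out$end >= 40)
  expect_equal(out$rank, 1L)

  # parent coordinates honour the profile offset
  sc <- rep(0, 60); sc[21:40] <- 6
  out <- callCandidates(mkProfile(sc, offset = 101L), threshold = 5)
  expect_equal(c(out$start, out$end), c(121, 140))
})

test_that("candidates never overlap and ranks order by descending score", {
  withr::local_seed(22)
  for (rep in 1:20) {
    s <- synthProtein(rep, 300, embed = "KLWKKLLKLFSKLWKQIKKV",
                      realistic = TRUE)
    out <- predictCaMBD(s, threshold = 3)
    if (nrow(out) < 2) next
    byPos <- out[order(out$start), ]
    expect_true(all(byPos$start[-1] > byPos$end[-nrow(byPos)]))
    expect_equal(out$score, sort(out$score, decreasing = TRUE))
    expect_true(all(out$length >= 18 & out$length <= 22))
  }
})

test_that("the predictor recovers embedded segments in synthetic proteins", {
  hits <- 0L
  for (seed in 1:30) {
    s <- synthProtein(seed, 400, embed = "KLWKKLLKLFSKLWKQIKKV")
    cand <- predictCaMBD(s)
    if (nrow(cand) == 0) next
    top <- cand[cand$rank == 1L, ]
    if (jaccardSpan(c(top$start, top$end), embeddedSpan(s)) >= 0.5)
      hits <- hits + 1L
  }
  expect_gte(hits, 27L)
})
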