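test_that("motif classes encode inclusive anchor numbering", {
  cls <- motifClasses()
  expect_named(cls, c("1-10", "1-12", "1-14", "1-16", "1-5-10", "1-8-13",
                      "1-8-14"))
  expect_equal(cls[["1-5-10"]]@anchorOffsets, c(0L, 4L, 9L))
  expect_equal(cls[["1-8-14"]]@anchorOffsets, c(0L, 7L, 13L))
  expect_equal(cls[["1-5-10"]]@parent, "1-10")
  expect_equal(cls[["1-8-14"]]@parent, "1-14")
  expect_true(is.na(cls[["1-8-13"]]@parent))
  expect_error(motifClasses("1-9"), "unknown motif class")
})

test_that("anchor sets hold the canonical hydrophobics", {
  expect_setequal(anchorSet("core")@letters, c("F", "I", "L", "V", "W"))
  expect_setequal(anchorSet("extended")@letters,
                  c("F", "I", "L", "V", "W", "M", "Y"))
})

test_that("enumeration finds the single 1-5-10 in the CaMKIIA domain", {
  camkii <- proteinSequence("CaMKIIA", "RRKLKGAILTTMLATR", offset = 296)
  m <- enumerateMatches(camkii, motifClasses("1-5-10"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$anchor_positions[[1]], c(299L, 303L, 308L))
  expect_equal(m$fingerprint, "LIL")
  # anchor-free sequence yields nothing
  expect_equal(nrow(enumerateMatches(
    proteinSequence("g", "GGGGGGGGGGGGGGGG"))), 0L)
})

test_that("raw enumeration of the ROCK1 domain matches the brute-force oracle", {
  rock1 <- proteinSequence("ROCK1-CaMBD1", "AFGEVQLVRHKSTRKVYAM",
                           offset = 86)
  m <- enumerateMatches(rock1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$class_name, c("1-12", "1-10"))  # span order at start 90, 92
  expect_equal(m$anchor_positions[[1]], c(90L, 101L))
  expect_equal(m$anchor_positions[[2]], c(92L, 101L))
  expect_equal(m$fingerprint, c("VV", "LV"))
  oracle <- bruteForceEnumerate("AFGEVQLVRHKSTRKVYAM", 86)
  expect_identical(
    matchKey(m),
    paste(oracle$class_name, oracle$anchors, oracle$fingerprint,
          oracle$span_start, oracle$span_end))
})

test_that("subsumption removes only coterminal refined two-anchor matches", {
  tgm2 <- proteinSequence("TGM2-CaMBD1", "KSINRSLIVGLKISTKSVGR",
                          offset = 414)
  raw <- enumerateMatches(tgm2)
  expect_setequal(paste(raw$class_name, raw$span_start),
                  c("1-16 416", "1-12 420", "1-10 422", "1-5-10 422"))
  cur <- applySubsumption(raw)
  expect_setequal(cur$class_name, c("1-16", "1-12", "1-5-10"))
  expect_equal(nrow(cur), 3L)

  # nothing to subsume -> identity
  rock1 <- proteinSequence("r", "AFGEVQLVRHKSTRKVYAM", offset = 86)
  raw2 <- enumerateMatches(rock1)
  expect_identical(matchKey(applySubsumption(raw2)), matchKey(raw2))

  # CaMKII: the raw 1-10 disappears under its coterminal 1-5-10
  camkii <- proteinSequence("c", "RRKLKGAILTTMLATR", offset = 296)
  raw3 <- enumerateMatches(camkii)
  expect_setequal(raw3$class_name, c("1-10", "1-5-10"))
  expect_equal(applySubsumption(raw3)$class_name, "1-5-10")
})

test_that("scanMotifs defaults to curated mode", {
  tgm2 <- proteinSequence("t", "KSINRSLIVGLKISTKSVGR", offset = 414)
  expect_equal(nrow(scanMotifs(tgm2)), 3L)
  expect_equal(nrow(scanMotifs(tgm2, mode = "raw")), 4L)
})

test_that("IQ scanning reports all overlapping windows, X never in classes", {
  expect_equal(scanIQ(proteinSequence("toy", "IQAAARGAAARAAF"))$start, 1L)
  expect_equal(nrow(scanIQ(proteinSequence("g", "GGGGGGGGGGGGGG"))), 0L)
  # X allowed at wildcard but not class positions
  expect_equal(nrow(scanIQ(proteinSequence("x1", "IQXXARGAAARAAF"))), 1L)
  expect_equal(nrow(scanIQ(proteinSequence("x2", "XQAAARGAAARAAF"))), 0L)
  # offset-aware reporting
  expect_equal(scanIQ(proteinSequence("o", "GIQAAARGAAARAAF",
                                      offset = 100))$start, 101L)
})

test_that("IQ scanner agrees with the window-checking oracle on a spliced case", {
  withr::local_seed(7)
  iq <- "LQGGGRGGGGKGGW"   # instantiated IQ window
  bg <- randomResidues(200, c("A", "C", "D", "E", "G", "H", "M", "N", "P",
                              "Q", "S", "T"))
  spliced <- paste0(substr(bg, 1, 100), iq, substr(bg, 115, 200))
  s <- proteinSequence("spliced", spliced)
  got <- scanIQ(s)$start
  expect_true(101L %in% got)
  expect_equal(got, iqOracle(spliced))
})

test_that("fingerprint tables group distinct anchor arrangements by class", {
  gsk <- proteinSequence("GSK3beta-CaMBD1", "LVAIKKVLQDKRFKNRELQI",
                         offset = 81)
  ft <- fingerprintTable(scanMotifs(gsk))
  expect_equal(ft[["1-5-10"]], "ILF")
  expect_true("VF" %in% ft[["1-12"]])
  expect_equal(fingerprintTable(scanMotifs(
    proteinSequence("c", "RRKLKGAILTTMLATR", offset = 296))),
    list("1-5-10" = "LIL"))
  expect_length(fingerprintTable(scanMotifs(proteinSequence("g", "GGGG"))),
                0L)
})

test_that("fingerprint comparison is per-class set algebra", {
  camkii <- list("1-5-10" = "LIL")
  gsk <- list("1-5-10" = "ILF")
  cmp <- compareFingerprints(camkii, gsk)
  expect_equal(cmp[["1-5-10"]]$shared, character(0))
  expect_equal(cmp[["1-5-10"]]$only_a, "LIL")
  expect_equal(cmp[["1-5-10"]]$only_b, "ILF")

  self <- compareFingerprints(gsk, gsk)
  expect_equal(self[["1-5-10"]]$only_a, character(0))
  expect_equal(self[["1-5-10"]]$only_b, character(0))

  cmp2 <- compareFingerprints(list("1-12" = c("VI", "VF")),
                              list("1-12" = "VF"))
  expect_equal(cmp2[["1-12"]]$shared, "VF")
  expect_equal(cmp2[["1-12"]]$only_a, "VI")
  # classes absent from one table are treated as empty
  cmp3 <- compareFingerprints(list("1-10" = "LL"), list())
  expect_equal(cmp3[["1-10"]]$only_a, "LL")
  expect_equal(cmp3[["1-10"]]$shared, character(0))
})
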