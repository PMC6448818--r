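NATIVE_CORE <- "CUGCUGCAGGU"

test_that("printed probe sequences reproduce the expected scan pattern", {
  probes <- emsaProbes()
  m <- buildMatrix(NATIVE_CORE, name = "d3u")

  native <- scanRegion(m, probes[["native_d3u"]], scanParams("exact"))
  expect_equal(nrow(native), 1L)
  expect_equal(native$offset, 10L)
  expect_equal(native$matched, NATIVE_CORE)
  expect_equal(native$mismatches, 0L)

  expect_equal(nrow(scanRegion(m, probes[["scrambled_d3u"]],
                               scanParams("exact"))), 0L)

  # the fly-box probe differs from the consensus at one core position
  off <- scanRegion(m, probes[["off_box"]], scanParams("exact"))
  expect_equal(nrow(off), 0L)
  off1 <- scanRegion(m, probes[["off_box"]],
                     scanParams("iupac", maxMismatch = 1))
  expect_equal(nrow(off1), 1L)
  expect_equal(off1$offset, 10L)
  expect_equal(off1$mismatches, 1L)
})

test_that("split scanning enforces order and the gap window", {
  probes <- emsaProbes()
  m <- buildMatrix(NATIVE_CORE, name = "d3u")
  sm <- splitMotif(m, 6, minGap = 0, maxGap = 0)

  sp <- scanSplit(sm, probes[["native_d3u"]], scanParams("exact"))
  expect_equal(nrow(sp$pairs), 1L)
  expect_equal(sp$pairs$offset_a, 10L)
  expect_equal(sp$pairs$offset_b, 16L)
  expect_equal(sp$pairs$gap, 0L)

  # CUG half destroyed: no pairs, CAGGU half still found
  mc <- scanSplit(sm, probes[["minus_cug"]], scanParams("exact"))
  expect_equal(nrow(mc$pairs), 0L)
  expect_equal(nrow(mc$halfA), 0L)
  expect_equal(mc$halfB$offset, 16L)
  expect_equal(mc$halfB$matched, "CAGGU")

  # wrong order: CAGGU 5' of CUGCUG never pairs
  wrong <- scanSplit(splitMotif(m, 6, 0, 50), "CAGGUAAAAACUGCUG",
                     scanParams("exact"))
  expect_equal(nrow(wrong$pairs), 0L)
  expect_equal(nrow(wrong$halfA), 1L)
  expect_equal(nrow(wrong$halfB), 1L)
})

test_that("log-odds scoring matches hand-computed values", {
  m1 <- buildMatrix(NATIVE_CORE, pseudocount = 0.25)
  # consensus window attains the column-max sum
  expect_equal(logOddsScore(m1, NATIVE_CORE), 11 * log2(0.625 / 0.25))
  # all-N window is worth 0 bits under the background policy
  expect_equal(logOddsScore(m1, strrep("N", 11),
                            nPolicy = "background_score"), 0)
  # two-instance matrix, pseudocount 0.25, uniform background:
  # 10 agreeing positions contribute log2((2.25/3)/0.25) each and the
  # split position 10 contributes log2((1.25/3)/0.25)
  m2 <- buildMatrix(c(NATIVE_CORE, "CUGCUGCAGCU"), pseudocount = 0.25)
  expected <- 10 * log2(3) + log2(5 / 3)
  expect_equal(logOddsScore(m2, NATIVE_CORE), expected, tolerance = 1e-9)

  expect_error(logOddsScore(m1, "CUG"), "length")
  m0 <- buildMatrix(NATIVE_CORE, pseudocount = 0)
  expect_error(logOddsScore(m0, NATIVE_CORE), "pseudocount")
})

test_that("scanning respects boundary and sorting contracts", {
  m <- buildMatrix(NATIVE_CORE, name = "d3u")
  expect_equal(nrow(scanRegion(m, "CUGCUG", scanParams("exact"))), 0L)
  tandem <- paste0(NATIVE_CORE, NATIVE_CORE, NATIVE_CORE)
  hits <- scanRegion(m, tandem, scanParams("exact"))
  expect_equal(hits$offset, c(0L, 11L, 22L))
  expect_true(all(hits$mismatches == 0L))
  # overlapping hits are all reported
  ovl <- scanRegion(buildMatrix("AAA"), "AAAAA", scanParams("exact"))
  expect_equal(ovl$offset, 0:2)
})

test_that("N-containing windows follow the configured policy", {
  m <- buildMatrix(NATIVE_CORE, pseudocount = 0.25)
  seqN <- paste0("AAA", sub("G", "N", NATIVE_CORE, fixed = TRUE), "AAA")
  expect_equal(nrow(scanRegion(m, seqN, scanParams("exact"))), 0L)
  expect_equal(nrow(scanRegion(m, seqN, scanParams("iupac",
                                                   maxMismatch = 3))), 0L)
  # under background_score an N merely contributes 0 bits
  hitsBg <- scanRegion(m, seqN, scanParams("pwm", pwmThreshold = 0.8,
                                           nPolicy = "background_score"))
  expect_equal(hitsBg$offset, 3L)
  hitsRej <- scanRegion(m, seqN, scanParams("pwm", pwmThreshold = 0.8,
                                            nPolicy = "reject_window"))
  expect_equal(nrow(hitsRej), 0L)
})

test_that("scanner agrees with the brute-force oracle across modes", {
  set.seed(2024)
  for (trial in 1:150) {
    L <- sample(4:12, 1)
    m <- randomMotifMatrix(L)
    params <- randomScanParams()
    seqStr <- randomRnaString(sample(c(12:300, 1500), 1),
                              withN = runif(1) < 0.3)
    got <- scanRegion(m, seqStr, params)$offset
    want <- oracleScan(m, seqStr, params)
    expect_identical(got, as.integer(want),
                     info = sprintf("trial %d mode %s", trial,
                                    slot(params, "mode")))
  }
})

test_that("raising the pwm threshold or shrinking the gap is monotone", {
  set.seed(77)
  m <- buildMatrix(c(NATIVE_CORE, "CUGCUGCAGCU"))
  sm10 <- splitMotif(m, 6, 0, 10)
  sm3 <- splitMotif(m, 6, 0, 3)
  for (trial in 1:20) {
    s <- randomRnaString(400)
    t1 <- sort(runif(1, 0.2, 0.6))
    t2 <- t1 + runif(1, 0, 0.35)
    lo <- scanRegion(m, s, scanParams("pwm", pwmThreshold = t1))$offset
    hi <- scanRegion(m, s, scanParams("pwm", pwmThreshold = t2))$offset
    expect_true(all(hi %in% lo))
    pWide <- scanSplit(sm10, s, scanParams("iupac", maxMismatch = 1))$pairs
    pNarrow <- scanSplit(sm3, s, scanParams("iupac", maxMismatch = 1))$pairs
    expect_true(nrow(pNarrow) <= nrow(pWide))
    if (nrow(pNarrow)) {
      key <- function(p) paste(p$offset_a, p$offset_b)
      expect_true(all(key(pNarrow) %in% key(pWide)))
    }
  }
})

test_that("zero-gap split of an indicator motif reproduces full hits", {
  set.seed(99)
  m <- buildMatrix(NATIVE_CORE, name = "d3u")
  sm <- splitMotif(m, 6, 0, 0)
  for (trial in 1:20) {
    s <- paste0(randomRnaString(80), NATIVE_CORE, randomRnaString(80))
    full <- scanRegion(m, s, scanParams("exact"))$offset
    pairs <- scanSplit(sm, s, scanParams("exact"))$pairs$offset_a
    expect_identical(sort(pairs), sort(full))
  }
})

test_that("conservation grading maps Hamming distance to bands", {
  ref <- NATIVE_CORE
  expect_equal(classifyConservation(NATIVE_CORE, ref),
               list(distance = 0L, grade = "exact"))
  expect_equal(classifyConservation("CUGCUGCAGCU", ref),
               list(distance = 1L, grade = "high"))
  expect_equal(classifyConservation("CUGCUGCAGCA", ref),
               list(distance = 2L, grade = "moderate"))
  expect_equal(classifyConservation("UCUUCACAGGU", ref),
               list(distance = 6L, grade = "weak"))
  expect_error(classifyConservation("CUG", ref), "length")
})

test_that("hit tables serialize to TSV and BED", {
  m <- buildMatrix(NATIVE_CORE, name = "d3u")
  hits <- scanRegion(m, regionSeq(emsaProbes()[["native_d3u"]],
                                  "probe1", "THREE_UTR"),
                     scanParams("exact"))
  tsv <- tempfile(fileext = ".tsv")
  writeHits(hits, tsv)
  back <- read.delim(tsv)
  expect_equal(back$offset_0based, 10L)
  expect_equal(back$end, 21L)
  bed <- tempfile(fileext = ".bed")
  writeHits(hits, bed, format = "bed")
  bl <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(bl[1:3], c("probe1|THREE_UTR", "10", "21"))
})
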