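test_that("simulation respects planting configuration and determinism", {
  # no planting -> empty truth
  s0 <- simulateTranscriptome(simConfig(nTranscripts = 5, seed = 1))
  expect_equal(nrow(s0$truth), 0L)

  # Poisson planting: total within 3 sd of n * rate
  s1 <- simulateTranscriptome(simConfig(nTranscripts = 100,
                                        plantRate = 1.0, seed = 12))
  expect_true(abs(nrow(s1$truth) - 100) <= 3 * sqrt(100))
  expect_true(all(s1$truth$region == "THREE_UTR"))

  # same seed -> byte-identical files
  cfg <- simConfig(nTranscripts = 10, plantRate = 0.5, seed = 33)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(simulateTranscriptome(cfg), d1)
  writeSimulation(simulateTranscriptome(cfg), d2)
  for (f in c("genome.fasta", "annotation.gff3", "truth.tsv",
              "config.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("planted instances sit at their truth offsets", {
  sim <- simulateTranscriptome(simConfig(nTranscripts = 30,
                                         plantRate = 1.2, seed = 8))
  byKey <- split(seq_len(nrow(sim$truth)),
                 paste(sim$truth$transcript_id, sim$truth$region))
  regKey <- paste(vapply(sim$regions, transcriptId, character(1)),
                  vapply(sim$regions, regionLabel, character(1)))
  for (k in names(byKey)) {
    reg <- sim$regions[[match(k, regKey)]]
    s <- as.character(regionSequence(reg))
    for (i in byKey[[k]]) {
      o <- sim$truth$offset[i]
      w <- nchar(sim$truth$planted_sequence[i])
      expect_equal(substr(s, o + 1, o + w), sim$truth$planted_sequence[i])
    }
  }
  # instances never overlap within a region
  for (k in names(byKey)) {
    rows <- sim$truth[byKey[[k]], ]
    rows <- rows[order(rows$offset), ]
    if (nrow(rows) > 1) {
      w <- nchar(rows$planted_sequence[-nrow(rows)])
      expect_true(all(rows$offset[-1] >= rows$offset[-nrow(rows)] + w))
    }
  }
})

test_that("simulated files parse cleanly and lengths are conserved", {
  cfg <- simConfig(nTranscripts = 15, plantRate = 1.0, seed = 21)
  sim <- simulateTranscriptome(cfg)
  d <- tempfile()
  p <- writeSimulation(sim, d)
  genome <- readGenome(p[["genome"]])
  models <- readAnnotation(p[["annotation"]])
  expect_length(models, 15)
  regKey <- paste(vapply(sim$regions, transcriptId, character(1)),
                  vapply(sim$regions, regionLabel, character(1)))
  for (tid in names(models)) {
    got <- extractRegions(models[[tid]], genome)
    for (lab in c("FIVE_UTR", "CDS", "THREE_UTR", "FULL")) {
      want <- sim$regions[[match(paste(tid, lab), regKey)]]
      expect_equal(as.character(regionSequence(got[[lab]])),
                   as.character(regionSequence(want)))
    }
    lens <- vapply(got, length, integer(1))
    expect_equal(sum(lens[c("FIVE_UTR", "CDS", "THREE_UTR")]),
                 lens[["FULL"]])
    expect_true(lens[["FIVE_UTR"]] >= 100 && lens[["FIVE_UTR"]] <= 200)
    expect_true(lens[["CDS"]] >= 300 && lens[["CDS"]] <= 600)
    expect_true(lens[["THREE_UTR"]] >= 200 && lens[["THREE_UTR"]] <= 400)
    # multi-exon transcripts always split a UTR across exons
    expect_gte(length(exons(models[[tid]])), 2L)
  }
})

test_that("a region too short for the planted element is rejected", {
  expect_error(
    simulateTranscriptome(simConfig(nTranscripts = 3,
                                    threeUtrRange = c(5L, 8L),
                                    plantRate = 1.0, seed = 1)),
    "too short")
})

test_that("background composition matches the configuration", {
  bg <- c(0.4, 0.1, 0.2, 0.3)
  sim <- simulateTranscriptome(simConfig(nTranscripts = 60,
                                         background = bg, seed = 55))
  full <- paste(vapply(sim$regions[vapply(sim$regions, regionLabel,
                                          character(1)) == "FULL"],
                       function(r) as.character(regionSequence(r)),
                       character(1)), collapse = "")
  n <- nchar(full)
  tab <- table(factor(strsplit(full, "")[[1]],
                      levels = c("A", "C", "G", "U")))
  for (i in 1:4) {
    se <- sqrt(bg[i] * (1 - bg[i]) / n)
    expect_lt(abs(tab[[i]] / n - bg[i]), 3 * se)
  }
})

test_that("first-order Markov backgrounds follow the transition matrix", {
  P <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.1, 0.1, 0.7, 0.1,
                0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE)
  sim <- simulateTranscriptome(simConfig(nTranscripts = 30,
                                         transitions = P, seed = 60))
  # per-transcript FULL sequences are contiguous draws from the chain
  fulls <- sim$regions[vapply(sim$regions, regionLabel,
                              character(1)) == "FULL"]
  from <- character(0); to <- character(0)
  for (r in fulls) {
    ch <- strsplit(as.character(regionSequence(r)), "")[[1]]
    from <- c(from, ch[-length(ch)])
    to <- c(to, ch[-1])
  }
  selA <- from == "A"
  pAA <- mean(to[selA] == "A")
  se <- sqrt(0.7 * 0.3 / sum(selA))
  expect_lt(abs(pAA - 0.7), 4 * se)
})

test_that("recovery scoring matches planted truth", {
  m <- buildMatrix("CUGCUGCAGGU", name = "d3u")
  sim <- simulateTranscriptome(simConfig(nTranscripts = 40,
                                         plantRate = 1.0, seed = 17))
  u3 <- sim$regions[vapply(sim$regions, regionLabel,
                           character(1)) == "THREE_UTR"]
  hits <- scanRegions(m, u3, scanParams("exact"))
  rep0 <- recoveryReport(hits, sim$truth)
  expect_equal(rep0$sensitivity, 1.0)
  expect_equal(rep0$nPlanted, nrow(sim$truth))

  # mutated instances: exact recall drops, mismatch-tolerant recall
  # dominates it on the same run
  simM <- simulateTranscriptome(simConfig(nTranscripts = 40,
                                          plantRate = 1.0,
                                          mutationRate = 0.2, seed = 18))
  u3m <- simM$regions[vapply(simM$regions, regionLabel,
                             character(1)) == "THREE_UTR"]
  exact <- recoveryReport(scanRegions(m, u3m, scanParams("exact")),
                          simM$truth)
  tol <- recoveryReport(
    scanRegions(m, u3m, scanParams("iupac", maxMismatch = 2)),
    simM$truth)
  expect_lt(exact$sensitivity, 1.0)
  expect_gte(tol$sensitivity, exact$sensitivity)

  # no hits at all: zero sensitivity, undefined precision
  none <- recoveryReport(scanRegions(m, list(), scanParams("exact")),
                         simM$truth)
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$precision))

  # disjoint transcript namespaces are rejected
  alien <- hits
  alien$transcript_id <- paste0("zz", alien$transcript_id)
  expect_error(recoveryReport(alien, sim$truth), "transcript identifiers")
})
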