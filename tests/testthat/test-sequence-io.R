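test_that("readGenome validates, normalizes and indexes contigs", {
  fa <- writeFastaFixture(c(c1 = strrep("ACGT", 10)))
  g <- readGenome(fa)
  expect_length(g, 1)
  expect_equal(length(g[["c1"]]), 40L)

  fa2 <- writeFastaFixture(c(c1 = "acgtACGT"))
  expect_equal(as.character(readGenome(fa2)[["c1"]]), "ACGTACGT")

  # U accepted, stored as T
  fa3 <- writeFastaFixture(c(c1 = "ACGU"))
  expect_equal(as.character(readGenome(fa3)[["c1"]]), "ACGT")

  fa4 <- writeFastaFixture(c(c1 = "ACGTACXT"))
  err <- expect_error(readGenome(fa4))
  expect_match(conditionMessage(err), "c1")
  expect_match(conditionMessage(err), "position 7")

  fa5 <- writeFastaFixture(c(c1 = "ACGT", c1 = "GGCC"))
  expect_error(readGenome(fa5), "duplicate contig")

  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(readGenome(empty))
})

test_that("GFF3 parsing builds transcript models with derived CDS span", {
  models <- readAnnotation(twoExonGff())
  expect_length(models, 1)
  m <- models[["t1"]]
  expect_equal(transcriptId(m), "t1")
  expect_equal(geneId(m), "g1")
  expect_equal(strand(m), "+")
  expect_equal(BiocGenerics::start(exons(m)), c(1L, 21L))
  expect_equal(BiocGenerics::end(exons(m)), c(10L, 30L))
  expect_equal(BiocGenerics::start(cdsSpan(m)), 5L)
  expect_equal(BiocGenerics::end(cdsSpan(m)), 25L)

  # transcripts without CDS are retained as non-coding
  nc <- readAnnotation(twoExonGff(withCds = FALSE))[["t1"]]
  expect_length(cdsSpan(nc), 0)
})

test_that("annotation structural errors are rejected", {
  bad1 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tt\tmRNA\t1\t30\t.\t+\t.\tID=t1",
               "c1\tt\texon\t1\t10\t.\t+\t.\tParent=t1",
               "c1\tt\texon\t8\t20\t.\t+\t.\tParent=t1"), bad1)
  expect_error(readAnnotation(bad1), "[Oo]verlapping exons")

  bad2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tt\tmRNA\t1\t30\t.\t+\t.\tID=t1",
               "c1\tt\texon\t1\t10\t.\t+\t.\tParent=t9"), bad2)
  expect_error(readAnnotation(bad2), "no parent mRNA")

  bad3 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tt\tmRNA\t1\t30\t.\t+\t.\tID=t1",
               "c1\tt\texon\t1\t10\t.\t+\t.\tParent=t1",
               "c1\tt\tCDS\t5\t15\t.\t+\t0\tParent=t1"), bad3)
  expect_error(readAnnotation(bad3), "CDS outside exon union")
})

test_that("explicit UTR features are checked against the derivation", {
  ok <- readAnnotation(twoExonGff(explicitUtrs = TRUE))
  expect_length(ok, 1)
  expect_error(readAnnotation(twoExonGff(explicitUtrs = TRUE,
                                         utr3End = 29L)),
               "disagree")
})

test_that("GTF dialect is accepted", {
  gtf <- tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "g1"; transcript_id "t1";'
  writeLines(c(
    paste0("c1\tt\ttranscript\t1\t30\t.\t+\t.\t", attr1),
    paste0("c1\tt\texon\t1\t10\t.\t+\t.\t", attr1),
    paste0("c1\tt\texon\t21\t30\t.\t+\t.\t", attr1),
    paste0("c1\tt\tCDS\t5\t10\t.\t+\t0\t", attr1),
    paste0("c1\tt\tCDS\t21\t25\t.\t+\t0\t", attr1)
  ), gtf)
  models <- readAnnotation(gtf, dialect = "gtf")
  m <- models[["t1"]]
  expect_equal(geneId(m), "g1")
  expect_equal(BiocGenerics::start(cdsSpan(m)), 5L)
  expect_equal(BiocGenerics::end(cdsSpan(m)), 25L)
})

test_that("region extraction stitches exons with the expected geometry", {
  genome <- readGenome(writeFastaFixture(c(c1 = TOY_CONTIG)))
  model <- readAnnotation(twoExonGff())[["t1"]]
  regions <- extractRegions(model, genome)
  lens <- vapply(regions, length, integer(1))
  expect_equal(lens, c(FIVE_UTR = 4L, CDS = 11L, THREE_UTR = 5L,
                       FULL = 20L))
  # FULL is the concatenation of the exonic sequence, T -> U
  exonic <- paste0(substr(TOY_CONTIG, 1, 10), substr(TOY_CONTIG, 21, 30))
  expect_equal(as.character(regionSequence(regions$FULL)),
               chartr("T", "U", exonic))
  expect_equal(paste0(as.character(regionSequence(regions$FIVE_UTR)),
                      as.character(regionSequence(regions$CDS)),
                      as.character(regionSequence(regions$THREE_UTR))),
               as.character(regionSequence(regions$FULL)))
})

test_that("minus-strand extraction mirrors the plus-strand fixture", {
  genome <- readGenome(writeFastaFixture(c(c1 = TOY_CONTIG)))
  plus <- readAnnotation(twoExonGff())[["t1"]]
  # reflect the fixture within the 30-nt contig: coordinates x -> 31 - x
  rcContig <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(TOY_CONTIG)))
  genome2 <- readGenome(writeFastaFixture(c(c1 = rcContig)))
  minus <- TranscriptModel("t1m", "g1", "c1", "-",
                           IRanges::IRanges(c(1L, 21L), c(10L, 30L)),
                           IRanges::IRanges(6L, 26L))
  rPlus <- extractRegions(plus, genome)
  rMinus <- extractRegions(minus, genome2)
  for (lab in c("FIVE_UTR", "CDS", "THREE_UTR", "FULL")) {
    expect_equal(as.character(regionSequence(rMinus[[lab]])),
                 as.character(regionSequence(rPlus[[lab]])),
                 label = lab)
  }
})

test_that("strand symmetry holds over random transcript fixtures", {
  set.seed(404)
  for (trial in 1:25) {
    n <- sample(60:200, 1)
    contig <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = "")
    # random non-overlapping exons
    k <- sample(1:4, 1)
    cuts <- sort(sample(seq_len(n - 1), 2 * k))
    starts <- cuts[seq(1, 2 * k, by = 2)]
    ends <- cuts[seq(2, 2 * k, by = 2)]
    exPlus <- IRanges::IRanges(starts, ends)
    exonPos <- unlist(Map(seq, starts, ends))
    if (length(exonPos) < 4) next
    cdsLo <- exonPos[2]
    cdsHi <- exonPos[length(exonPos) - 1]
    plus <- TranscriptModel("t", "g", "c1", "+", exPlus,
                            IRanges::IRanges(cdsLo, cdsHi))
    gPlus <- readGenome(writeFastaFixture(c(c1 = contig)))
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(contig)))
    minus <- TranscriptModel("t", "g", "c1", "-",
                             IRanges::IRanges(sort(n - ends + 1),
                                              sort(n - starts + 1)),
                             IRanges::IRanges(n - cdsHi + 1, n - cdsLo + 1))
    gMinus <- readGenome(writeFastaFixture(c(c1 = rc)))
    rP <- extractRegions(plus, gPlus)
    rM <- extractRegions(minus, gMinus)
    for (lab in c("FIVE_UTR", "CDS", "THREE_UTR", "FULL")) {
      expect_equal(as.character(regionSequence(rM[[lab]])),
                   as.character(regionSequence(rP[[lab]])))
    }
    # length conservation
    expect_equal(length(rP$FIVE_UTR) + length(rP$CDS) +
                   length(rP$THREE_UTR), length(rP$FULL))
    expect_equal(length(rP$FULL), sum(BiocGenerics::width(exPlus)))
  }
})

test_that("non-coding transcripts yield FULL only", {
  genome <- readGenome(writeFastaFixture(c(c1 = TOY_CONTIG)))
  nc <- readAnnotation(twoExonGff(withCds = FALSE))[["t1"]]
  regions <- extractRegions(nc, genome)
  expect_equal(length(regions$FULL), 20L)
  expect_equal(length(regions$FIVE_UTR), 0L)
  expect_equal(length(regions$CDS), 0L)
  expect_equal(length(regions$THREE_UTR), 0L)
})

test_that("extraction errors name the offending input", {
  genome <- readGenome(writeFastaFixture(c(c2 = TOY_CONTIG)))
  model <- readAnnotation(twoExonGff())[["t1"]]
  expect_error(extractRegions(model, genome), "missing from the genome")
  shortG <- readGenome(writeFastaFixture(c(c1 = "ACGTACGT")))
  expect_error(extractRegions(model, shortG), "out of contig bounds")
})

test_that("region FASTA round trip reproduces sequences exactly", {
  genome <- readGenome(writeFastaFixture(c(c1 = TOY_CONTIG)))
  regions <- extractRegions(readAnnotation(twoExonGff())[["t1"]], genome)
  f <- tempfile(fileext = ".fasta")
  writeRegions(regions, f)
  back <- readRegions(f)
  expect_length(back, 4)
  for (i in seq_along(back)) {
    orig <- regions[[regionLabel(back[[i]])]]
    expect_equal(as.character(regionSequence(back[[i]])),
                 as.character(regionSequence(orig)))
    expect_equal(transcriptId(back[[i]]), transcriptId(orig))
  }
  idx <- regionIndex(regions)
  expect_equal(idx$length[idx$region == "CDS"], 11L)
})
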