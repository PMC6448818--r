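# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the packaged probe/core FASTA files.

# Write a FASTA file from a named character vector; returns the path.
writeFastaFixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Hand-built two-exon gene used across the annotation tests:
# exons 1-10 and 21-30, CDS bases 5-25 (so CDS pieces are 5-10 and
# 21-25), giving region lengths 5'UTR 4, CDS 11, 3'UTR 5 on the plus
# strand.
twoExonGff <- function(path = tempfile(fileext = ".gff3"),
                       strand = "+", withCds = TRUE,
                       explicitUtrs = FALSE, utr3End = 30L) {
  lines <- c(
    "##gff-version 3",
    sprintf("c1\ttest\tgene\t1\t30\t.\t%s\t.\tID=g1", strand),
    sprintf("c1\ttest\tmRNA\t1\t30\t.\t%s\t.\tID=t1;Parent=g1", strand),
    sprintf("c1\ttest\texon\t1\t10\t.\t%s\t.\tParent=t1", strand),
    sprintf("c1\ttest\texon\t21\t30\t.\t%s\t.\tParent=t1", strand)
  )
  if (withCds) {
    lines <- c(lines,
      sprintf("c1\ttest\tCDS\t5\t10\t.\t%s\t0\tParent=t1", strand),
      sprintf("c1\ttest\tCDS\t21\t25\t.\t%s\t0\tParent=t1", strand))
  }
  if (explicitUtrs) {
    lines <- c(lines,
      sprintf("c1\ttest\tfive_prime_UTR\t1\t4\t.\t%s\t.\tParent=t1", strand),
      sprintf("c1\ttest\tthree_prime_UTR\t26\t%d\t.\t%s\t.\tParent=t1",
              utr3End, strand))
  }
  writeLines(lines, path)
  path
}

# 30-nt contig used with twoExonGff(); chosen with all four bases
# represented so reverse-complement differences are visible.
TOY_CONTIG <- "ACGTACGTAGGGGGGGGGGTTTTACGATCC"

randomRnaString <- function(n, withN = FALSE) {
  alpha <- c("A", "C", "G", "U", if (withN) "N")
  prob <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

randomMotifMatrix <- function(L, pseudocount = 0.25, nInstances = 4L) {
  inst <- vapply(seq_len(nInstances), function(i) randomRnaString(L),
                 character(1))
  buildMatrix(inst, pseudocount = pseudocount,
              name = sprintf("rand%d", L))
}

randomScanParams <- function() {
  mode <- sample(c("exact", "iupac", "pwm"), 1L)
  scanParams(
    mode = mode,
    pwmThreshold = stats::runif(1L, 0.2, 0.95),
    thresholdType = "fraction",
    maxMismatch = sample(0:3, 1L),
    nPolicy = sample(c("reject_window", "background_score"), 1L),
    minFrac = stats::runif(1L, 0.25, 0.75)
  )
}
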