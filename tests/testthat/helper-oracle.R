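# Independent brute-force scanner used as the oracle in equivalence
# tests. Deliberately written from first principles: per-window loops,
# its own IUPAC table and its own consensus/threshold derivations,
# sharing no code with the package's vectorized scanner.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "U"), S = c("C", "G"),
  Y = c("C", "U"), K = c("G", "U"), V = c("A", "C", "G"),
  H = c("A", "C", "U"), D = c("A", "G", "U"), B = c("C", "G", "U"),
  N = c("A", "C", "G", "U")
)

# Degenerate consensus by direct rule application (letters with
# probability >= minFrac; argmax fallback, first of A,C,G,U on ties).
oracleConsensus <- function(probs, minFrac) {
  bases <- c("A", "C", "G", "U")
  vapply(seq_len(nrow(probs)), function(i) {
    inc <- bases[probs[i, ] >= minFrac - 1e-12]
    if (length(inc) == 0L) inc <- bases[which.max(probs[i, ])]
    hit <- NULL
    for (nm in names(ORACLE_IUPAC)) {
      if (setequal(ORACLE_IUPAC[[nm]], inc)) hit <- nm
    }
    hit
  }, character(1))
}

# Returns sorted 0-based offsets of matching windows.
oracleScan <- function(matrix, seqStr, params) {
  bases <- c("A", "C", "G", "U")
  probs <- motifProbs(matrix)
  bg <- motifBackground(matrix)
  L <- motifLength(matrix)
  chars <- strsplit(toupper(seqStr), "")[[1L]]
  n <- length(chars) - L + 1L
  if (n < 1L) return(integer(0))
  mode <- slot(params, "mode")
  consSingle <- vapply(seq_len(L), function(i) {
    bases[which.max(probs[i, ])]
  }, character(1))
  if (mode == "iupac") {
    consDeg <- oracleConsensus(probs, slot(params, "minFrac"))
  }
  if (mode == "pwm") {
    maxScore <- 0
    for (i in seq_len(L)) {
      maxScore <- maxScore + max(log2(probs[i, ] / bg))
    }
    thr <- if (slot(params, "thresholdType") == "fraction") {
      slot(params, "pwmThreshold") * maxScore
    } else {
      slot(params, "pwmThreshold")
    }
  }
  hits <- integer(0)
  for (o in 0:(n - 1L)) {
    win <- chars[(o + 1L):(o + L)]
    ok <- FALSE
    if (mode == "exact") {
      ok <- all(win == consSingle)
    } else if (mode == "iupac") {
      if (!any(win == "N")) {
        mm <- 0L
        for (i in seq_len(L)) {
          if (!(win[i] %in% ORACLE_IUPAC[[consDeg[i]]])) mm <- mm + 1L
        }
        ok <- mm <= slot(params, "maxMismatch")
      }
    } else {
      hasN <- any(win == "N")
      if (!(hasN && slot(params, "nPolicy") == "reject_window")) {
        sc <- 0
        for (i in seq_len(L)) {
          if (win[i] != "N") {
            j <- match(win[i], bases)
            sc <- sc + log2(probs[i, j] / bg[j])
          }
        }
        ok <- sc >= thr - 1e-9
      }
    }
    if (ok) hits <- c(hits, o)
  }
  hits
}
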