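#' Build a position weight matrix from aligned motif instances
#'
#' Counts nucleotides per alignment column and smooths with a per-cell
#' pseudocount: `probs[i, x] = (counts[i, x] + pseudocount) /
#' (n + 4 * pseudocount)`. All instances must be equal-length RNA
#' strings over A, C, G, U (ambiguity codes and N are not allowed in
#' instances).
#'
#' The default pseudocount of 0.25 keeps log-odds scores finite off the
#' consensus even for a single-instance (indicator) matrix; pass
#' `pseudocount = 0` for exact counting.
#'
#' @param instances character vector of equal-length RNA strings.
#' @param pseudocount nonnegative per-cell pseudocount (default 0.25).
#' @param background length-4 background probabilities (A, C, G, U),
#'   default uniform.
#' @param name motif label.
#' @return a [MotifMatrix-class].
#' @examples
#' m <- buildMatrix(c("CUGCUGCAGGU", "CUGCUGCAGCU"), pseudocount = 0)
#' motifProbs(m)[10, ]  # G and C each 0.5
#' @export
buildMatrix <- function(instances, pseudocount = 0.25,
                        background = rep(0.25, 4), name = "motif") {
  if (length(instances) < 1L) {
    stop("at least one motif instance is required")
  }
  instances <- toupper(as.character(instances))
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L) {
    stop("motif instances must all have the same length (got lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  L <- lens[1L]
  if (L < 1L) stop("motif instances must be nonempty")
  bad <- grepl("[^ACGU]", instances)
  if (any(bad)) {
    stop("illegal character in motif instance ", which(bad)[1L],
         " ('", instances[which(bad)[1L]], "'); alphabet is A, C, G, U")
  }
  chars <- matrix(unlist(strsplit(instances, "")), nrow = length(instances),
                  byrow = TRUE)
  counts <- vapply(seq_len(L), function(i) {
    tab <- table(factor(chars[, i], levels = RNA_BASES))
    as.numeric(tab)
  }, numeric(4))
  counts <- t(counts)
  dimnames(counts) <- list(NULL, RNA_BASES)
  n <- length(instances)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  background <- background / sum(background)
  names(background) <- RNA_BASES
  new("MotifMatrix", name = name, counts = counts, probs = probs,
      background = background, pseudocount = pseudocount)
}

#' Degenerate IUPAC consensus of a motif matrix
#'
#' At each position, returns the IUPAC code covering all letters whose
#' probability is at least `minFrac`; when no letter reaches `minFrac`,
#' the most probable letter is used (ties broken by fixed alphabet order
#' A < C < G < U, so the result is deterministic but lossy for tied
#' columns).
#'
#' @param matrix a [MotifMatrix-class].
#' @param minFrac minimum probability for inclusion, in (0, 1].
#' @return a single degenerate RNA string of length `motifLength(matrix)`.
#' @examples
#' m <- buildMatrix(c("CUGCUGCAGGU", "CUGCUGCAGCU"), pseudocount = 0)
#' consensusIupac(m)  # "CUGCUGCAGSU"
#' @export
consensusIupac <- function(matrix, minFrac = 0.5) {
  stopifnot(is(matrix, "MotifMatrix"))
  if (minFrac <= 0 || minFrac > 1) stop("minFrac must lie in (0, 1]")
  probs <- matrix@probs
  codes <- vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    letters <- RNA_BASES[p >= minFrac - 1e-12]
    if (!length(letters)) letters <- RNA_BASES[which.max(p)]
    IUPAC_FROM_SET[[paste(sort(letters), collapse = "")]]
  }, character(1))
  paste(codes, collapse = "")
}

# Single-letter consensus: per-position argmax, ties by alphabet order.
.consensusLetters <- function(matrix) {
  probs <- matrix@probs
  RNA_BASES[apply(probs, 1L, which.max)]
}

#' Per-position and total information content of a motif matrix
#'
#' Relative entropy against the matrix's background:
#' `IC_i = sum_x p[i, x] * log2(p[i, x] / b[x])` with `0 * log(0) := 0`.
#'
#' @param matrix a [MotifMatrix-class].
#' @return list with `perPosition` (numeric vector, bits) and `total`.
#' @export
informationContent <- function(matrix) {
  stopifnot(is(matrix, "MotifMatrix"))
  probs <- matrix@probs
  bg <- matrix@background
  if (any(bg == 0 & colSums(probs) > 0)) {
    stop("background entry is 0 where the matrix has nonzero probability")
  }
  ic <- vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / bg[nz]))
  }, numeric(1))
  list(perPosition = ic, total = sum(ic))
}

#' Scrambled (column-permuted) control motifs
#'
#' Generates composition-matched null motifs by uniformly permuting the
#' position columns of the matrix, excluding the identity permutation.
#' Controls preserve the column multiset and hence the total information
#' content exactly, which makes them an assumption-light null for
#' occurrence-count enrichment. Deterministic given `seed`.
#'
#' @param matrix a [MotifMatrix-class] with at least 2 positions.
#' @param nControls number of controls (>= 1).
#' @param seed RNG seed.
#' @return list of [MotifMatrix-class], named `"<name>_scr<k>"`.
#' @export
scrambleControls <- function(matrix, nControls = 99L, seed = 1L) {
  stopifnot(is(matrix, "MotifMatrix"))
  L <- nrow(matrix@counts)
  if (L < 2L) stop("cannot scramble a length-1 motif (no non-identity ",
                   "permutation exists)")
  if (nControls < 1L) stop("nControls must be >= 1")
  .withSeed(seed, {
    lapply(seq_len(nControls), function(k) {
      repeat {
        perm <- sample.int(L)
        if (!identical(perm, seq_len(L))) break
      }
      new("MotifMatrix",
          name = paste0(matrix@name, "_scr", k),
          counts = matrix@counts[perm, , drop = FALSE],
          probs = matrix@probs[perm, , drop = FALSE],
          background = matrix@background,
          pseudocount = matrix@pseudocount)
    })
  })
}

#' Split a motif matrix into a bipartite half-site pair
#'
#' Partitions the matrix at `splitIndex`: half A holds positions
#' `1..splitIndex` and half B positions `splitIndex + 1..L`. The default
#' split of the 11-nt D3U-box at position 6 yields the CUG-repeat half
#' (`CUGCUG`) and the `CAGGU` half, each of which is bound by a distinct
#' RNA-binding protein.
#'
#' @param matrix a [MotifMatrix-class].
#' @param splitIndex 1-based last position of the 5' half; must satisfy
#'   `1 <= splitIndex <= L - 1`.
#' @param minGap,maxGap allowed gap (nt) between half hits when scanned
#'   with [scanSplit()].
#' @return a [SplitMotif-class].
#' @export
splitMotif <- function(matrix, splitIndex = 6L, minGap = 0L, maxGap = 10L) {
  stopifnot(is(matrix, "MotifMatrix"))
  L <- nrow(matrix@counts)
  splitIndex <- as.integer(splitIndex)
  if (splitIndex < 1L || splitIndex > L - 1L) {
    stop("splitIndex must lie in [1, ", L - 1L, "], got ", splitIndex)
  }
  half <- function(idx, tag) {
    new("MotifMatrix", name = paste0(matrix@name, "_", tag),
        counts = matrix@counts[idx, , drop = FALSE],
        probs = matrix@probs[idx, , drop = FALSE],
        background = matrix@background, pseudocount = matrix@pseudocount)
  }
  new("SplitMotif",
      halfA = half(seq_len(splitIndex), "halfA"),
      halfB = half((splitIndex + 1L):L, "halfB"),
      minGap = as.integer(minGap), maxGap = as.integer(maxGap))
}

#' Read aligned motif instances from FASTA or plain text
#'
#' Accepts aligned FASTA or one-sequence-per-line text (auto-detected
#' from the first non-blank character); `T` is accepted and converted to
#' `U`.
#'
#' @param path input file.
#' @return character vector of upper-case RNA strings.
#' @export
readMotifInstances <- function(path) {
  if (!file.exists(path)) stop("instance file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("instance file is empty: ", path)
  if (startsWith(lines[1L], ">")) {
    seqs <- as.character(readBStringSet(path))
  } else {
    seqs <- lines
  }
  toupper(.dnaToRna(unname(seqs)))
}

#' Write / read a motif matrix in minimal MEME-like text
#'
#' The format is: a name line, an `ALPHABET= ACGU` line, a background
#' line, a `letter-probability matrix` header carrying the length and
#' pseudocount, then `L` rows of 4 probabilities. `readMotifMatrix()`
#' inverts `writeMotifMatrix()`; counts are reconstructed from the
#' stored probabilities, pseudocount and instance count.
#'
#' @param matrix a [MotifMatrix-class].
#' @param path output (input) file.
#' @return `writeMotifMatrix()` returns `path` invisibly;
#'   `readMotifMatrix()` returns a [MotifMatrix-class].
#' @export
writeMotifMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "MotifMatrix"))
  n <- sum(matrix@counts[1L, ])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("MOTIF ", matrix@name),
    "ALPHABET= ACGU",
    paste0("background: ",
           paste(formatC(matrix@background, digits = 10, format = "g"),
                 collapse = " ")),
    paste0("letter-probability matrix: alength= 4 w= ",
           nrow(matrix@probs), " nsites= ",
           formatC(n, digits = 10, format = "g"), " pseudocount= ",
           formatC(matrix@pseudocount, digits = 10, format = "g"))
  ), con)
  utils::write.table(format(matrix@probs, digits = 12, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeMotifMatrix
#' @export
readMotifMatrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  name <- sub("^MOTIF\\s+", "", lines[1L])
  bg <- as.numeric(strsplit(sub("^background:\\s+", "", lines[3L]),
                            "\\s+")[[1L]])
  hdr <- lines[4L]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
  n <- as.numeric(sub(".*nsites=\\s*([0-9.eE+-]+).*", "\\1", hdr))
  pc <- as.numeric(sub(".*pseudocount=\\s*([0-9.eE+-]+).*", "\\1", hdr))
  probs <- do.call(rbind, lapply(lines[5:(4 + w)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  }))
  colnames(probs) <- RNA_BASES
  counts <- probs * (n + 4 * pc) - pc
  counts[abs(counts) < 1e-9] <- 0
  colnames(counts) <- RNA_BASES
  new("MotifMatrix", name = name, counts = counts, probs = probs,
      background = setNames(bg, RNA_BASES), pseudocount = pc)
}

#' Trim maximal shared flanks from a set of probe sequences
#'
#' Finds the longest prefix and suffix common to all sequences and
#' returns the variable cores between them. Applied to the four printed
#' electrophoretic-mobility-shift probe sequences this recovers the
#' 11-nt variable core of the D3U-box element.
#'
#' @param probes character vector of equal-length RNA strings (>= 2).
#' @return list with `prefix`, `suffix` (shared flanks) and `cores`
#'   (character vector of trimmed variable cores).
#' @export
trimSharedFlanks <- function(probes) {
  probes <- toupper(as.character(probes))
  if (length(probes) < 2L) stop("need at least 2 probe sequences")
  if (length(unique(nchar(probes))) != 1L) {
    stop("probe sequences must have equal length")
  }
  n <- nchar(probes[1L])
  chars <- matrix(unlist(strsplit(probes, "")), nrow = length(probes),
                  byrow = TRUE)
  same <- apply(chars, 2L, function(col) all(col == col[1L]))
  pre <- if (all(same)) n else which(!same)[1L] - 1L
  suf <- if (all(same)) 0L else n - max(which(!same))
  list(prefix = substr(probes[1L], 1L, pre),
       suffix = substr(probes[1L], n - suf + 1L, n),
       cores = substr(probes, pre + 1L, n - suf))
}

#' Printed probe and core fixtures
#'
#' `emsaProbes()` returns the four 31-nt RNA probe sequences used in the
#' binding assays (native D3U-box, olive-fruit-fly box, scrambled box,
#' minus-CUG box); `motifCores()` returns the two 11-nt D3U-box core
#' variants used as the default matrix instance set. Both are also
#' shipped as FASTA under `inst/extdata/`.
#'
#' @return named character vector of RNA strings.
#' @export
emsaProbes <- function() {
  x <- readBStringSet(system.file("extdata", "emsa_probes.fasta",
                                  package = "utrmotif", mustWork = TRUE))
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname emsaProbes
#' @export
motifCores <- function() {
  x <- readBStringSet(system.file("extdata", "d3u_core_instances.fasta",
                                  package = "utrmotif", mustWork = TRUE))
  setNames(toupper(as.character(x)), names(x))
}
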