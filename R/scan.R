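#' Construct scanning parameters
#'
#' Three modes are supported. `"exact"` matches the single-letter
#' consensus with zero mismatches. `"iupac"` matches the degenerate
#' consensus (letters with probability >= `minFrac` per position)
#' allowing up to `maxMismatch` mismatching positions. `"pwm"` keeps
#' windows whose summed log-odds score reaches the threshold, expressed
#' either as a fraction of the matrix's maximum attainable score
#' (comparable across column-permuted matrices, so this is the form
#' used for scrambled controls) or as absolute bits.
#'
#' Windows containing N never match in exact/iupac modes; in pwm mode
#' the `nPolicy` decides between rejecting such windows (default) and
#' scoring N as 0 bits (the background-score policy).
#'
#' @param mode `"exact"`, `"iupac"` or `"pwm"`.
#' @param pwmThreshold pwm threshold (default 0.8 of max score).
#' @param thresholdType `"fraction"` or `"bits"`.
#' @param maxMismatch iupac-mode mismatch tolerance (default 0).
#' @param nPolicy `"reject_window"` or `"background_score"`.
#' @param minFrac consensus inclusion threshold for iupac mode.
#' @return a [ScanParams-class].
#' @export
scanParams <- function(mode = c("iupac", "exact", "pwm"),
                       pwmThreshold = 0.8,
                       thresholdType = c("fraction", "bits"),
                       maxMismatch = 0L,
                       nPolicy = c("reject_window", "background_score"),
                       minFrac = 0.5) {
  new("ScanParams", mode = match.arg(mode), pwmThreshold = pwmThreshold,
      thresholdType = match.arg(thresholdType),
      maxMismatch = as.integer(maxMismatch), nPolicy = match.arg(nPolicy),
      minFrac = minFrac)
}

#' Log-odds score of a window against a motif matrix
#'
#' `score = sum_i log2(probs[i, w_i] / background[w_i])` in bits. An `N`
#' in the window contributes 0 bits under the `background_score` policy
#' and is an error under `reject_window` (callers screen such windows
#' out before scoring).
#'
#' @param matrix a [MotifMatrix-class]; probabilities must be strictly
#'   positive (build with a pseudocount > 0).
#' @param window RNA string of length `motifLength(matrix)`.
#' @param nPolicy `"reject_window"` or `"background_score"`.
#' @return score in bits.
#' @export
logOddsScore <- function(matrix, window,
                         nPolicy = c("background_score", "reject_window")) {
  stopifnot(is(matrix, "MotifMatrix"))
  nPolicy <- match.arg(nPolicy)
  window <- toupper(as.character(window))
  L <- nrow(matrix@probs)
  if (nchar(window) != L) {
    stop("window length ", nchar(window), " does not match motif length ", L)
  }
  if (any(matrix@probs == 0)) {
    stop("zero probability in matrix '", matrix@name,
         "'; rebuild with pseudocount > 0 for log-odds scoring")
  }
  codes <- .encodeRNA(window)
  if (any(codes == 5L) && nPolicy == "reject_window") {
    stop("window contains N and nPolicy is reject_window")
  }
  lod <- .lodMatrix(matrix)
  sum(lod[cbind(codes, seq_len(L))])
}

# 5 x L log-odds lookup (rows A, C, G, U, N); the N row is 0 so that an
# N contributes nothing under the background_score policy.
.lodMatrix <- function(matrix) {
  lod <- t(log2(matrix@probs / rep(matrix@background,
                                   each = nrow(matrix@probs))))
  rbind(lod, N = 0)
}

.maxScore <- function(matrix) {
  sum(apply(log2(matrix@probs / rep(matrix@background,
                                    each = nrow(matrix@probs))), 1L, max))
}

# TRUE for each window start whose L-window contains an N.
.windowHasN <- function(codes, L, n) {
  cs <- cumsum(codes == 5L)
  (cs[seq_len(n) + L - 1L] - c(0L, cs[seq_len(n - 1L)])) > 0L
}

# Core vectorized scan over integer codes. Returns data.frame of
# 0-based offsets plus score/mismatch columns. Hamming distance to the
# single-letter consensus is computed only for kept windows.
.scanCodes <- function(matrix, codes, params) {
  L <- nrow(matrix@probs)
  n <- length(codes) - L + 1L
  if (n < 1L) {
    return(data.frame(offset = integer(0), score = numeric(0),
                      mismatches = integer(0)))
  }
  cons <- match(.consensusLetters(matrix), RNA_BASES)
  score <- NULL
  if (params@mode == "exact") {
    mm <- integer(n)
    for (i in seq_len(L)) {
      mm <- mm + (codes[i:(i + n - 1L)] != cons[i])
    }
    keep <- mm == 0L
  } else if (params@mode == "iupac") {
    allowed <- .allowedMatrix(matrix, params@minFrac)
    am <- integer(n)
    for (i in seq_len(L)) {
      am <- am + !allowed[codes[i:(i + n - 1L)] + 5L * (i - 1L)]
    }
    keep <- am <= params@maxMismatch
    if (any(codes == 5L)) keep <- keep & !.windowHasN(codes, L, n)
  } else {
    if (any(matrix@probs == 0)) {
      stop("zero probability in matrix '", matrix@name,
           "'; pwm mode requires pseudocount > 0")
    }
    lod <- .lodMatrix(matrix)
    sc <- numeric(n)
    for (i in seq_len(L)) {
      sc <- sc + lod[codes[i:(i + n - 1L)] + 5L * (i - 1L)]
    }
    thr <- if (params@thresholdType == "fraction") {
      params@pwmThreshold * .maxScore(matrix)
    } else {
      params@pwmThreshold
    }
    keep <- sc >= thr - 1e-9
    if (params@nPolicy == "reject_window" && any(codes == 5L)) {
      keep <- keep & !.windowHasN(codes, L, n)
    }
    score <- sc
  }
  off <- which(keep) - 1L
  mmOut <- vapply(off, function(o) {
    sum(codes[(o + 1L):(o + L)] != cons)
  }, integer(1))
  data.frame(offset = off,
             score = if (is.null(score)) rep(NA_real_, length(off)) else
               score[off + 1L],
             mismatches = mmOut)
}

# 5 x L logical: is code allowed at position i under the degenerate
# consensus? N (row 5) is never allowed.
.allowedMatrix <- function(matrix, minFrac) {
  cons <- consensusIupac(matrix, minFrac)
  codes <- strsplit(cons, "")[[1L]]
  allowed <- vapply(codes, function(cd) {
    RNA_BASES %in% strsplit(IUPAC_EXPAND[[cd]], "")[[1L]]
  }, logical(4))
  rbind(allowed, N = FALSE)
}

# Accept a RegionSequence, RNAString or plain character as scan input.
.asRegionSequence <- function(x) {
  if (is(x, "RegionSequence")) return(x)
  regionSeq(x)
}

#' Scan a region sequence for motif occurrences
#'
#' Tests every length-`L` window of the sense strand (the element is an
#' RNA motif within transcribed sequence, so no reverse-complement scan
#' is performed). All overlapping hits are reported, sorted by offset.
#' Offsets are 0-based within the region; `end` is the 0-based half-open
#' end. The `mismatches` column always reports Hamming distance to the
#' single-letter consensus; `score` is filled in pwm mode only.
#'
#' @param matrix a [MotifMatrix-class].
#' @param region a [RegionSequence-class] (or a plain RNA string, which
#'   is wrapped as a `FULL` region named `"query"`).
#' @param params a [ScanParams-class].
#' @return hit `data.frame` with columns `transcript_id`, `region`,
#'   `offset`, `end`, `matched`, `score`, `mismatches`, `motif_name`.
#' @examples
#' m <- buildMatrix("CUGCUGCAGGU", name = "d3u")
#' scanRegion(m, "UGGUUCACGUCUGCUGCAGGUCUCUGACUCU", scanParams("exact"))
#' @export
scanRegion <- function(matrix, region, params = scanParams()) {
  stopifnot(is(matrix, "MotifMatrix"), is(params, "ScanParams"))
  region <- .asRegionSequence(region)
  seqStr <- as.character(region@sequence)
  hits <- .scanCodes(matrix, .encodeRNA(seqStr), params)
  if (!nrow(hits)) return(.emptyHits())
  L <- nrow(matrix@probs)
  data.frame(
    transcript_id = region@transcriptId, region = region@region,
    offset = hits$offset, end = hits$offset + L,
    matched = substring(seqStr, hits$offset + 1L, hits$offset + L),
    score = hits$score, mismatches = hits$mismatches,
    motif_name = matrix@name, stringsAsFactors = FALSE
  )
}

#' @param regions a flat list of [RegionSequence-class] objects.
#' @rdname scanRegion
#' @export
scanRegions <- function(matrix, regions, params = scanParams()) {
  out <- lapply(regions, function(r) scanRegion(matrix, r, params))
  do.call(rbind, c(list(.emptyHits()), out))
}

#' Scan for co-occurring half-sites of a split motif
#'
#' Scans both halves independently, then reports ordered pairs in which
#' half B lies strictly 3' of half A with a gap (nt between the end of A
#' and the start of B) inside `[minGap, maxGap]`. The half-only hit
#' lists are returned alongside for diagnostics. With indicator halves
#' partitioning a consensus and a gap window of `[0, 0]`, the pairs
#' reproduce the exact-mode hits of the intact motif.
#'
#' @param splitMotif a [SplitMotif-class].
#' @param region a [RegionSequence-class] or RNA string.
#' @param params a [ScanParams-class] applied to both halves.
#' @return list with `pairs` (a `data.frame` with offsets of both
#'   halves, the gap, and the matched substrings), `halfA` and `halfB`
#'   (hit tables of the individual halves).
#' @export
scanSplit <- function(splitMotif, region, params = scanParams()) {
  stopifnot(is(splitMotif, "SplitMotif"))
  region <- .asRegionSequence(region)
  hitsA <- scanRegion(splitMotif@halfA, region, params)
  hitsB <- scanRegion(splitMotif@halfB, region, params)
  La <- nrow(splitMotif@halfA@probs)
  pairs <- data.frame(
    transcript_id = character(0), region = character(0),
    offset_a = integer(0), offset_b = integer(0), gap = integer(0),
    matched_a = character(0), matched_b = character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(hitsA) && nrow(hitsB)) {
    grid <- expand.grid(a = seq_len(nrow(hitsA)), b = seq_len(nrow(hitsB)))
    gap <- hitsB$offset[grid$b] - (hitsA$offset[grid$a] + La)
    ok <- gap >= splitMotif@minGap & gap <= splitMotif@maxGap
    if (any(ok)) {
      ga <- grid$a[ok]
      gb <- grid$b[ok]
      pairs <- data.frame(
        transcript_id = region@transcriptId, region = region@region,
        offset_a = hitsA$offset[ga], offset_b = hitsB$offset[gb],
        gap = gap[ok], matched_a = hitsA$matched[ga],
        matched_b = hitsB$matched[gb], stringsAsFactors = FALSE
      )
      pairs <- pairs[order(pairs$offset_a, pairs$offset_b), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  list(pairs = pairs, halfA = hitsA, halfB = hitsB)
}

#' Grade a hit by conservation relative to a reference consensus
#'
#' Operationalizes qualitative conservation language as Hamming-distance
#' bands (a repository convention): 0 mismatches is `"exact"`, 1 is
#' `"high"`, 2 is `"moderate"` and 3 or more is `"weak"`.
#'
#' @param matched matched RNA substring (or a one-row hit table from
#'   [scanRegion()]).
#' @param referenceConsensus single-letter reference consensus of the
#'   same length.
#' @return list with `distance` (integer) and `grade` (character).
#' @export
classifyConservation <- function(matched, referenceConsensus) {
  if (is.data.frame(matched)) {
    if (nrow(matched) != 1L) stop("supply a single hit or string")
    matched <- matched$matched
  }
  matched <- toupper(as.character(matched))
  referenceConsensus <- toupper(as.character(referenceConsensus))
  if (nchar(matched) != nchar(referenceConsensus)) {
    stop("matched sequence and reference consensus lengths differ (",
         nchar(matched), " vs ", nchar(referenceConsensus), ")")
  }
  d <- .hamming(matched, referenceConsensus)
  grade <- if (d == 0L) "exact" else if (d == 1L) "high" else
    if (d == 2L) "moderate" else "weak"
  list(distance = as.integer(d), grade = grade)
}

#' Write a hit table as TSV or BED6
#'
#' TSV columns follow the hit-table contract (`offset` is 0-based,
#' `end` half-open). BED6 uses region-local 0-based half-open
#' coordinates with the region label folded into the name.
#'
#' @param hits hit `data.frame` from [scanRegion()]/[scanRegions()].
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- hits
    names(out)[names(out) == "offset"] <- "offset_0based"
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(
      chrom = paste0(hits$transcript_id, "|", hits$region),
      start = hits$offset, end = hits$end,
      name = hits$motif_name,
      score = ifelse(is.na(hits$score), 0, round(hits$score, 3)),
      strand = "+", stringsAsFactors = FALSE
    )
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
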