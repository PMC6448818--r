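#' utrmotif: weight-matrix scanning and scrambled-control enrichment for
#' UTR cis-regulatory motifs
#'
#' The package implements a transcript-region motif analysis pipeline:
#' position weight matrices built from aligned RNA motif instances
#' ([buildMatrix()]), stitched 5'UTR/CDS/3'UTR extraction from genome +
#' GFF3 annotation ([readAnnotation()], [extractRegions()]), exact /
#' IUPAC / log-odds scanning including a bipartite "split" mode
#' ([scanRegion()], [scanSplit()]), enrichment against column-permuted
#' scrambled control motifs ([enrichmentTest()], [regionProfile()]), and
#' a seeded synthetic-transcriptome generator with planted-motif truth
#' ([simulateTranscriptome()], [recoveryReport()]).
#'
#' @import methods
#' @importFrom stats rpois runif setNames
#' @importFrom utils read.table write.table packageVersion
#' @importFrom Biostrings DNAString DNAStringSet RNAString RNAStringSet
#'   readBStringSet readRNAStringSet writeXStringSet reverseComplement
#'   subseq
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics start end width strand
#' @importFrom S4Vectors mcols mcols<- Rle
#' @importFrom GenomicRanges GRanges
#' @importFrom rtracklayer import export
#' @importFrom jsonlite write_json read_json
#' @importFrom tools md5sum
#' @name utrmotif-package
#' @aliases utrmotif
#' @keywords internal
"_PACKAGE"

#' MotifMatrix: position count/probability matrix for an RNA motif
#'
#' A motif of length `L` over the fixed alphabet (A, C, G, U) with raw
#' per-position counts, pseudocount-smoothed probabilities and a
#' background composition. Probabilities are
#' `(counts + pseudocount) / (n + 4 * pseudocount)` per position.
#'
#' @slot name motif label.
#' @slot counts `L x 4` nonnegative count matrix, columns A, C, G, U.
#' @slot probs `L x 4` probability matrix; rows sum to 1.
#' @slot background length-4 background probabilities summing to 1.
#' @slot pseudocount nonnegative per-cell pseudocount used for `probs`.
#'
#' @seealso [buildMatrix()], [consensusIupac()], [scrambleControls()]
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(
    name = "character",
    counts = "matrix",
    probs = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("MotifMatrix", function(object) {
  msg <- character(0)
  L <- nrow(object@counts)
  if (L < 1L) msg <- c(msg, "motif length must be >= 1")
  if (ncol(object@counts) != 4L || ncol(object@probs) != 4L) {
    msg <- c(msg, "counts and probs must have 4 columns (A, C, G, U)")
  }
  if (!identical(colnames(object@counts), RNA_BASES) ||
      !identical(colnames(object@probs), RNA_BASES)) {
    msg <- c(msg, "column names must be A, C, G, U in order")
  }
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (nrow(object@probs) != L) msg <- c(msg, "counts/probs row mismatch")
  if (L >= 1L && ncol(object@probs) == 4L &&
      any(abs(rowSums(object@probs) - 1) > 1e-9)) {
    msg <- c(msg, "each probs row must sum to 1 (tol 1e-9)")
  }
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9 ||
      any(object@background < 0)) {
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  }
  if (length(object@pseudocount) != 1L || object@pseudocount < 0) {
    msg <- c(msg, "pseudocount must be a single nonnegative number")
  }
  if (length(msg)) msg else TRUE
})

#' SplitMotif: bipartite (half-site) representation of a motif
#'
#' Two independently scannable half matrices separated by a bounded gap,
#' used for motifs articulated around two cis-regulatory sequences (for
#' the D3U-box: a CUG-repeat half and a CAGGU half).
#'
#' @slot halfA 5' half [MotifMatrix-class].
#' @slot halfB 3' half [MotifMatrix-class].
#' @slot minGap minimum gap between halves, nt (>= 0).
#' @slot maxGap maximum gap between halves, nt (>= minGap).
#'
#' @seealso [splitMotif()], [scanSplit()]
#' @exportClass SplitMotif
setClass("SplitMotif",
  representation(
    halfA = "MotifMatrix",
    halfB = "MotifMatrix",
    minGap = "integer",
    maxGap = "integer"
  )
)

setValidity("SplitMotif", function(object) {
  msg <- character(0)
  if (object@minGap < 0L) msg <- c(msg, "minGap must be >= 0")
  if (object@maxGap < object@minGap) msg <- c(msg, "maxGap must be >= minGap")
  if (length(msg)) msg else TRUE
})

#' ScanParams: parameters controlling motif scanning
#'
#' @slot mode `"exact"`, `"iupac"` or `"pwm"`.
#' @slot pwmThreshold threshold for pwm mode; interpreted per
#'   `thresholdType`.
#' @slot thresholdType `"fraction"` (fraction of the matrix's maximum
#'   attainable score, in (0, 1]) or `"bits"` (absolute log-odds bits).
#' @slot maxMismatch maximum mismatches tolerated in iupac mode.
#' @slot nPolicy `"reject_window"` (windows containing N never match) or
#'   `"background_score"` (N scores 0 bits in pwm mode).
#' @slot minFrac minimum per-position probability for a letter to enter
#'   the degenerate IUPAC consensus used in iupac mode.
#'
#' @seealso [scanParams()], [scanRegion()]
#' @exportClass ScanParams
setClass("ScanParams",
  representation(
    mode = "character",
    pwmThreshold = "numeric",
    thresholdType = "character",
    maxMismatch = "integer",
    nPolicy = "character",
    minFrac = "numeric"
  )
)

setValidity("ScanParams", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("exact", "iupac", "pwm")) {
    msg <- c(msg, "mode must be exact, iupac or pwm")
  }
  if (!object@thresholdType %in% c("fraction", "bits")) {
    msg <- c(msg, "thresholdType must be fraction or bits")
  }
  if (object@thresholdType == "fraction" &&
      (object@pwmThreshold <= 0 || object@pwmThreshold > 1)) {
    msg <- c(msg, "fraction-of-max threshold must lie in (0, 1]")
  }
  if (object@maxMismatch < 0L) msg <- c(msg, "maxMismatch must be >= 0")
  if (!object@nPolicy %in% c("reject_window", "background_score")) {
    msg <- c(msg, "nPolicy must be reject_window or background_score")
  }
  if (object@minFrac <= 0 || object@minFrac > 1) {
    msg <- c(msg, "minFrac must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' TranscriptModel: exon/CDS structure of one transcript on a contig
#'
#' Genomic coordinates are 1-based inclusive (GFF3 convention). Exons
#' are stored sorted in ascending genomic order regardless of strand;
#' `cdsSpan` holds the genomic interval from the first to the last CDS
#' base, or is empty for non-coding transcripts.
#'
#' @slot transcriptId transcript identifier.
#' @slot geneId parent gene identifier (`NA` if unknown).
#' @slot contigId contig/chromosome identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon intervals, ascending,
#'   non-overlapping.
#' @slot cdsSpan [IRanges::IRanges] of length 0 or 1.
#'
#' @seealso [readAnnotation()], [extractRegions()]
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId = "character",
    contigId = "character",
    strand = "character",
    exons = "IRanges",
    cdsSpan = "IRanges"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character(0)
  ex <- object@exons
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (length(ex) < 1L) msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    if (is.unsorted(BiocGenerics::start(ex))) {
      msg <- c(msg, "exons must be sorted in ascending genomic order")
    }
    if (any(BiocGenerics::start(ex)[-1L] <=
            BiocGenerics::end(ex)[-length(ex)])) {
      msg <- c(msg, paste0("overlapping exons in transcript '",
                           object@transcriptId, "'"))
    }
  }
  if (length(object@cdsSpan) > 1L) msg <- c(msg, "cdsSpan must have length <= 1")
  if (length(object@cdsSpan) == 1L) {
    lo <- BiocGenerics::start(object@cdsSpan)
    hi <- BiocGenerics::end(object@cdsSpan)
    hitsExon <- any(BiocGenerics::start(ex) <= hi & BiocGenerics::end(ex) >= lo)
    if (!hitsExon) msg <- c(msg, "cdsSpan does not intersect the exon union")
  }
  if (length(msg)) msg else TRUE
})

#' RegionSequence: a stitched transcript region in 5'->3' orientation
#'
#' Holds the RNA sequence of one region (5'UTR, CDS, 3'UTR or the full
#' exonic sequence) of one transcript, stitched across exons and
#' reverse-complemented for minus-strand transcripts, together with the
#' ordered genomic intervals that contributed bases (in transcript
#' orientation).
#'
#' @slot transcriptId transcript identifier.
#' @slot region one of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"FULL"`.
#' @slot sequence [Biostrings::RNAString] in transcript orientation.
#' @slot sourceIntervals [IRanges::IRanges], ordered 5'->3' along the
#'   transcript; widths sum to the sequence length.
#'
#' @seealso [extractRegions()]
#' @exportClass RegionSequence
setClass("RegionSequence",
  representation(
    transcriptId = "character",
    region = "character",
    sequence = "RNAString",
    sourceIntervals = "IRanges"
  )
)

setValidity("RegionSequence", function(object) {
  msg <- character(0)
  if (!object@region %in% REGION_LABELS) {
    msg <- c(msg, "region must be FIVE_UTR, CDS, THREE_UTR or FULL")
  }
  if (length(object@sequence) !=
      sum(BiocGenerics::width(object@sourceIntervals))) {
    msg <- c(msg, "sequence length must equal total source interval width")
  }
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: observed vs scrambled-control motif occurrence
#'
#' Result of comparing a target motif's occurrence count in one region
#' class against the counts of column-permuted control motifs scanned
#' with identical parameters. The empirical p-value uses the add-one
#' formula `(1 + #\{controls >= observed\}) / (1 + n_controls)` and so
#' never reaches 0; fold enrichment is `observed / mean(controls)`, with
#' `NA` as the undefined sentinel when the control mean is 0.
#'
#' @slot motifName target motif label.
#' @slot region region class the counts refer to.
#' @slot observedCount observed count (integer >= 0).
#' @slot controlCounts integer vector, one count per control motif.
#' @slot foldEnrichment fold over the control mean (`NA` if undefined).
#' @slot empiricalP add-one empirical p-value in (0, 1].
#' @slot nControls number of control motifs.
#' @slot countingMode `"transcripts_with_hit"` or `"total_hits"`.
#'
#' @seealso [enrichmentTest()], [regionProfile()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(
    motifName = "character",
    region = "character",
    observedCount = "integer",
    controlCounts = "integer",
    foldEnrichment = "numeric",
    empiricalP = "numeric",
    nControls = "integer",
    countingMode = "character"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character(0)
  if (length(object@controlCounts) != object@nControls) {
    msg <- c(msg, "controlCounts length must equal nControls")
  }
  if (object@observedCount < 0L) msg <- c(msg, "observedCount must be >= 0")
  if (object@empiricalP <= 0 || object@empiricalP > 1) {
    msg <- c(msg, "empiricalP must lie in (0, 1]")
  }
  if (!object@countingMode %in% c("transcripts_with_hit", "total_hits")) {
    msg <- c(msg, "countingMode must be transcripts_with_hit or total_hits")
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic transcriptome generator
#'
#' @slot nTranscripts number of transcripts to simulate.
#' @slot exonCountRange integer `c(min, max)` exons per transcript.
#' @slot fiveUtrRange,cdsRange,threeUtrRange per-region length ranges in
#'   nt, `c(min, max)`.
#' @slot background length-4 order-0 nucleotide composition (A, C, G, U).
#' @slot transitions optional 4x4 first-order Markov transition matrix
#'   (rows = current base, columns = next base); a 0x0 matrix selects the
#'   order-0 model.
#' @slot plantRate named numeric (FIVE_UTR, CDS, THREE_UTR): expected
#'   planted instances per region (Poisson mean).
#' @slot mutationRate per-position substitution probability applied to
#'   planted instances.
#' @slot plantSequence RNA string planted (default: the native D3U-box
#'   core).
#' @slot intronRange intron length range, nt.
#' @slot spacerLength intergenic spacer length, nt.
#' @slot seed RNG seed making the simulation fully deterministic.
#'
#' @seealso [simConfig()], [simulateTranscriptome()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nTranscripts = "integer",
    exonCountRange = "integer",
    fiveUtrRange = "integer",
    cdsRange = "integer",
    threeUtrRange = "integer",
    background = "numeric",
    transitions = "matrix",
    plantRate = "numeric",
    mutationRate = "numeric",
    plantSequence = "character",
    intronRange = "integer",
    spacerLength = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be >= 1")
  rng <- function(x, nm, lo = 1L) {
    if (length(x) != 2L || x[1L] > x[2L] || x[1L] < lo) {
      paste0(nm, " must be c(min, max) with min <= max and min >= ", lo)
    } else character(0)
  }
  msg <- c(msg, rng(object@exonCountRange, "exonCountRange"),
           rng(object@fiveUtrRange, "fiveUtrRange"),
           rng(object@cdsRange, "cdsRange"),
           rng(object@threeUtrRange, "threeUtrRange"),
           rng(object@intronRange, "intronRange"))
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9 || any(object@background < 0)) {
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  }
  if (nrow(object@transitions) > 0L) {
    if (!all(dim(object@transitions) == c(4L, 4L)) ||
        any(abs(rowSums(object@transitions) - 1) > 1e-9) ||
        any(object@transitions < 0)) {
      msg <- c(msg, "transitions must be a 4x4 stochastic matrix")
    }
  }
  if (!identical(names(object@plantRate),
                 c("FIVE_UTR", "CDS", "THREE_UTR")) ||
      any(object@plantRate < 0)) {
    msg <- c(msg,
      "plantRate must be nonnegative and named FIVE_UTR, CDS, THREE_UTR")
  }
  if (object@mutationRate < 0 || object@mutationRate > 1) {
    msg <- c(msg, "mutationRate must lie in [0, 1]")
  }
  if (!grepl("^[ACGU]+$", object@plantSequence)) {
    msg <- c(msg, "plantSequence must be a nonempty RNA string over ACGU")
  }
  if (object@spacerLength < 1L) msg <- c(msg, "spacerLength must be >= 1")
  if (length(msg)) msg else TRUE
})
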