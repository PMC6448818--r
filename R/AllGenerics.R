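#' @describeIn MotifMatrix-class motif label.
#' @param object,x a package object.
#' @export
setGeneric("motifName", function(object) standardGeneric("motifName"))

#' @describeIn MotifMatrix-class motif length (number of positions).
#' @export
setGeneric("motifLength", function(object) standardGeneric("motifLength"))

#' @describeIn MotifMatrix-class raw `L x 4` count matrix.
#' @export
setGeneric("motifCounts", function(object) standardGeneric("motifCounts"))

#' @describeIn MotifMatrix-class smoothed `L x 4` probability matrix.
#' @export
setGeneric("motifProbs", function(object) standardGeneric("motifProbs"))

#' @describeIn MotifMatrix-class background composition.
#' @export
setGeneric("motifBackground",
           function(object) standardGeneric("motifBackground"))

#' @export
#' @rdname TranscriptModel-class
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))

#' @export
#' @rdname TranscriptModel-class
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' @export
#' @rdname TranscriptModel-class
setGeneric("contigId", function(object) standardGeneric("contigId"))

#' @export
#' @rdname TranscriptModel-class
setGeneric("exons", function(object) standardGeneric("exons"))

#' @export
#' @rdname TranscriptModel-class
setGeneric("cdsSpan", function(object) standardGeneric("cdsSpan"))

#' @export
#' @rdname RegionSequence-class
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))

#' @export
#' @rdname RegionSequence-class
setGeneric("regionSequence",
           function(object) standardGeneric("regionSequence"))

setMethod("motifName", "MotifMatrix", function(object) object@name)
setMethod("motifLength", "MotifMatrix", function(object) nrow(object@counts))
setMethod("motifCounts", "MotifMatrix", function(object) object@counts)
setMethod("motifProbs", "MotifMatrix", function(object) object@probs)
setMethod("motifBackground", "MotifMatrix", function(object) object@background)

setMethod("transcriptId", "TranscriptModel",
          function(object) object@transcriptId)
setMethod("geneId", "TranscriptModel", function(object) object@geneId)
setMethod("contigId", "TranscriptModel", function(object) object@contigId)
setMethod("exons", "TranscriptModel", function(object) object@exons)
setMethod("cdsSpan", "TranscriptModel", function(object) object@cdsSpan)

#' @describeIn TranscriptModel-class strand of the transcript.
#' @param x a `TranscriptModel`.
#' @export
setMethod("strand", "TranscriptModel", function(x) x@strand)

setMethod("transcriptId", "RegionSequence",
          function(object) object@transcriptId)
setMethod("regionLabel", "RegionSequence", function(object) object@region)
setMethod("regionSequence", "RegionSequence", function(object) object@sequence)

#' @describeIn RegionSequence-class region length in nt.
#' @export
setMethod("length", "RegionSequence", function(x) length(x@sequence))

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix '", object@name, "' (", nrow(object@counts),
      " positions)\n", sep = "")
  cat("  consensus:  ", consensusIupac(object), "\n", sep = "")
  ic <- informationContent(object)
  cat("  information: ", sprintf("%.2f", ic$total), " bits total\n", sep = "")
  cat("  pseudocount: ", object@pseudocount, "\n", sep = "")
})

setMethod("show", "SplitMotif", function(object) {
  cat("SplitMotif: ", consensusIupac(object@halfA), " ... ",
      consensusIupac(object@halfB), "  gap [", object@minGap, ", ",
      object@maxGap, "] nt\n", sep = "")
})

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: mode=", object@mode, sep = "")
  if (object@mode == "pwm") {
    cat(", threshold=", object@pwmThreshold, " (", object@thresholdType, ")",
        sep = "")
  }
  if (object@mode == "iupac") {
    cat(", maxMismatch=", object@maxMismatch, ", minFrac=", object@minFrac,
        sep = "")
  }
  cat(", nPolicy=", object@nPolicy, "\n", sep = "")
})

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId, " (gene ", object@geneId,
      ") on ", object@contigId, object@strand, "\n", sep = "")
  cat("  exons: ", length(object@exons), " (",
      sum(BiocGenerics::width(object@exons)), " nt exonic)\n", sep = "")
  if (length(object@cdsSpan)) {
    cat("  CDS span: ", BiocGenerics::start(object@cdsSpan), "-",
        BiocGenerics::end(object@cdsSpan), "\n", sep = "")
  } else {
    cat("  non-coding (no CDS)\n")
  }
})

setMethod("show", "RegionSequence", function(object) {
  n <- length(object@sequence)
  prev <- if (n > 40L) {
    paste0(as.character(subseq(object@sequence, 1L, 40L)), "...")
  } else {
    as.character(object@sequence)
  }
  cat("RegionSequence ", object@transcriptId, " ", object@region, " (", n,
      " nt): ", prev, "\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
  fold <- if (is.na(object@foldEnrichment)) "undefined" else
    sprintf("%.3f", object@foldEnrichment)
  cat("EnrichmentResult '", object@motifName, "' in ", object@region,
      " (", object@countingMode, ")\n", sep = "")
  cat("  observed: ", object@observedCount, "  control mean: ",
      sprintf("%.2f", mean(object@controlCounts)), " (n=", object@nControls,
      ")\n", sep = "")
  cat("  fold: ", fold, "  empirical p: ",
      sprintf("%.4f", object@empiricalP), "\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nTranscripts, " transcripts, ",
      object@exonCountRange[1L], "-", object@exonCountRange[2L],
      " exons, seed ", object@seed, "\n", sep = "")
  cat("  region nt: 5'UTR ", object@fiveUtrRange[1L], "-",
      object@fiveUtrRange[2L], ", CDS ", object@cdsRange[1L], "-",
      object@cdsRange[2L], ", 3'UTR ", object@threeUtrRange[1L], "-",
      object@threeUtrRange[2L], "\n", sep = "")
  cat("  plant rates: ", paste(names(object@plantRate), object@plantRate,
                               sep = "=", collapse = ", "),
      "; mutation ", object@mutationRate, "\n", sep = "")
})
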