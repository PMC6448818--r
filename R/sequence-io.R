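#' Read a genome FASTA into a validated DNAStringSet
#'
#' Sequences are upper-cased; `U` is accepted on input and stored as `T`
#' (genome storage stays DNA); any character outside A, C, G, T, N is
#' rejected with the contig and offset named. Contig identifiers are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet], one element per contig.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("genome FASTA contains no records: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate contig identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- vapply(seq_along(raw), function(i) {
    s <- chartr("Uu", "Tt", toupper(as.character(raw[[i]])))
    if (!nchar(s)) stop("contig '", ids[i], "' is empty")
    m <- regexpr("[^ACGTN]", s)
    if (m > 0L) {
      stop("contig '", ids[i], "': illegal character '",
           substr(s, m, m), "' at position ", as.integer(m))
    }
    s
  }, character(1))
  DNAStringSet(setNames(seqs, ids))
}

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,contigId identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons [IRanges::IRanges] of exon intervals (1-based inclusive);
#'   sorted ascending internally.
#' @param cdsSpan optional [IRanges::IRanges] of length 1 giving the
#'   genomic span from first to last CDS base; `NULL` for non-coding
#'   transcripts.
#' @return a [TranscriptModel-class].
#' @export
TranscriptModel <- function(transcriptId, geneId = NA_character_, contigId,
                            strand, exons, cdsSpan = NULL) {
  exons <- exons[order(BiocGenerics::start(exons))]
  if (is.null(cdsSpan)) cdsSpan <- IRanges()
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      geneId = as.character(geneId), contigId = as.character(contigId),
      strand = strand, exons = exons, cdsSpan = cdsSpan)
}

#' Read transcript annotation from GFF3 (or GTF) into TranscriptModels
#'
#' Builds one [TranscriptModel-class] per mRNA/transcript feature, with
#' exons attached through `Parent` attributes (GFF3) or `transcript_id`
#' (GTF). The CDS span is the first-to-last CDS base of the transcript.
#' UTRs are always derived from exon/CDS geometry; when explicit
#' `five_prime_UTR` / `three_prime_UTR` features are present they are
#' checked for consistency with that derivation and any disagreement is
#' an error (annotation dumps vary in whether UTR features are present,
#' so the derivation is the single source of truth).
#'
#' @param path GFF3 or GTF file.
#' @param dialect `"gff3"` (default) or `"gtf"`.
#' @return named list of [TranscriptModel-class] objects.
#' @export
readAnnotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = dialect)
  type <- as.character(gr$type)
  if (dialect == "gtf") {
    txParent <- gr$transcript_id
    geneOf <- gr$gene_id
    isTx <- type %in% c("transcript", "mRNA")
    txIds <- unique(txParent[type %in% c("exon", "CDS")])
    txGene <- vapply(txIds, function(t) {
      g <- unique(geneOf[!is.na(txParent) & txParent == t])
      if (length(g)) g[1L] else NA_character_
    }, character(1))
    parentOf <- function(sel) txParent[sel]
  } else {
    ids <- gr$ID
    parents <- gr$Parent  # CharacterList
    isTx <- type %in% c("mRNA", "transcript")
    txIds <- ids[isTx]
    if (anyNA(txIds)) stop("mRNA feature without an ID attribute")
    txGene <- vapply(which(isTx), function(i) {
      p <- parents[[i]]
      if (length(p)) p[1L] else NA_character_
    }, character(1))
    names(txGene) <- txIds
    parentOf <- function(sel) {
      vapply(which(sel), function(i) {
        p <- parents[[i]]
        if (length(p) == 0L) NA_character_ else p[1L]
      }, character(1))
    }
  }

  pick <- function(what) {
    sel <- type == what
    list(sel = sel,
         parent = if (any(sel)) parentOf(sel) else character(0),
         start = BiocGenerics::start(gr)[sel],
         end = BiocGenerics::end(gr)[sel],
         contig = as.character(GenomicRanges::seqnames(gr))[sel],
         strand = as.character(BiocGenerics::strand(gr))[sel])
  }
  ex <- pick("exon")
  cds <- pick("CDS")
  u5 <- pick("five_prime_UTR")
  u3 <- pick("three_prime_UTR")

  orphan <- !is.na(ex$parent) & !(ex$parent %in% txIds)
  orphan <- orphan | is.na(ex$parent)
  if (any(orphan)) {
    stop("exon at ", ex$contig[orphan][1L], ":", ex$start[orphan][1L],
         "-", ex$end[orphan][1L], " has no parent mRNA/transcript")
  }

  models <- lapply(txIds, function(t) {
    sel <- ex$parent == t
    if (!any(sel)) stop("transcript '", t, "' has no exon features")
    exons <- IRanges(ex$start[sel], ex$end[sel])
    contig <- unique(ex$contig[sel])
    std <- unique(ex$strand[sel])
    if (length(contig) != 1L) {
      stop("transcript '", t, "' has exons on multiple contigs")
    }
    if (length(std) != 1L || !std %in% c("+", "-")) {
      stop("transcript '", t, "' must have a single strand of + or -")
    }
    csel <- cds$parent == t
    span <- NULL
    if (any(csel)) {
      lo <- min(cds$start[csel])
      hi <- max(cds$end[csel])
      exSorted <- exons[order(BiocGenerics::start(exons))]
      # every CDS piece must fall inside the exon union
      inExon <- vapply(which(csel), function(i) {
        any(BiocGenerics::start(exSorted) <= cds$start[i] &
            BiocGenerics::end(exSorted) >= cds$end[i])
      }, logical(1))
      if (!all(inExon)) {
        stop("CDS outside exon union in transcript '", t, "'")
      }
      span <- IRanges(lo, hi)
    }
    m <- TranscriptModel(t, txGene[[t]], contig, std, exons, span)
    .checkExplicitUtrs(m, u5, u3, t)
    m
  })
  names(models) <- txIds
  models
}

# Explicit UTR features, when present, must equal the exon-minus-CDS
# derivation on the appropriate side.
.checkExplicitUtrs <- function(model, u5, u3, t) {
  if (!length(model@cdsSpan)) return(invisible(NULL))
  derived <- .regionGenomicIntervals(model)
  cmp <- function(feat, lab) {
    sel <- !is.na(feat$parent) & feat$parent == t
    if (!any(sel)) return(invisible(NULL))
    got <- IRanges::reduce(IRanges(feat$start[sel], feat$end[sel]))
    want <- IRanges::reduce(derived[[lab]])
    if (!identical(as.data.frame(got)[, 1:2], as.data.frame(want)[, 1:2])) {
      stop("explicit ", lab, " features of transcript '", t,
           "' disagree with the exon/CDS-derived UTR")
    }
  }
  cmp(u5, "FIVE_UTR")
  cmp(u3, "THREE_UTR")
  invisible(NULL)
}

# Genomic intervals (ascending order) contributing to each region.
# Returns a list FIVE_UTR/CDS/THREE_UTR/FULL of IRanges.
.regionGenomicIntervals <- function(model) {
  ex <- model@exons
  full <- ex
  if (!length(model@cdsSpan)) {
    empty <- IRanges()
    return(list(FIVE_UTR = empty, CDS = empty, THREE_UTR = empty,
                FULL = full))
  }
  lo <- BiocGenerics::start(model@cdsSpan)
  hi <- BiocGenerics::end(model@cdsSpan)
  clip <- function(a, b) {
    s <- pmax(BiocGenerics::start(ex), a)
    e <- pmin(BiocGenerics::end(ex), b)
    keep <- s <= e
    IRanges(s[keep], e[keep])
  }
  upstream <- clip(1L, lo - 1L)          # genomic left of the CDS span
  inside <- clip(lo, hi)
  downstream <- clip(hi + 1L, .Machine$integer.max)
  if (model@strand == "+") {
    list(FIVE_UTR = upstream, CDS = inside, THREE_UTR = downstream,
         FULL = full)
  } else {
    list(FIVE_UTR = downstream, CDS = inside, THREE_UTR = upstream,
         FULL = full)
  }
}

#' Extract stitched region sequences for a transcript
#'
#' Stitches exonic sequence into the four region classes in transcript
#' (5'->3') orientation: `FIVE_UTR` is the exonic sequence 5' of the CDS
#' span, `CDS` the exonic sequence within it, `THREE_UTR` the exonic
#' sequence 3' of it, and `FULL` all exonic sequence. Minus-strand
#' transcripts are reverse-complemented; output is RNA (T -> U).
#' Transcripts without a CDS yield `FULL` only, with the other three
#' regions empty. `|5'UTR| + |CDS| + |3'UTR| = |FULL|` always holds for
#' coding transcripts.
#'
#' @param model a [TranscriptModel-class].
#' @param genome named [Biostrings::DNAStringSet] from [readGenome()].
#' @return named list of four [RegionSequence-class] objects
#'   (`FIVE_UTR`, `CDS`, `THREE_UTR`, `FULL`).
#' @export
extractRegions <- function(model, genome) {
  stopifnot(is(model, "TranscriptModel"))
  if (!model@contigId %in% names(genome)) {
    stop("contig '", model@contigId, "' of transcript '",
         model@transcriptId, "' is missing from the genome")
  }
  contig <- genome[[model@contigId]]
  if (max(BiocGenerics::end(model@exons)) > length(contig) ||
      min(BiocGenerics::start(model@exons)) < 1L) {
    stop("exon out of contig bounds for transcript '",
         model@transcriptId, "'")
  }
  intervals <- .regionGenomicIntervals(model)
  lapply(setNames(nm = REGION_LABELS), function(lab) {
    iv <- intervals[[lab]]
    if (length(iv) == 0L) {
      dna <- DNAString("")
    } else {
      parts <- vapply(seq_along(iv), function(i) {
        as.character(subseq(contig, BiocGenerics::start(iv)[i],
                            BiocGenerics::end(iv)[i]))
      }, character(1))
      dna <- DNAString(paste(parts, collapse = ""))
    }
    if (model@strand == "-") {
      dna <- reverseComplement(dna)
      iv <- rev(iv)  # transcript orientation runs genomically right-to-left
    }
    new("RegionSequence", transcriptId = model@transcriptId, region = lab,
        sequence = RNAString(.dnaToRna(as.character(dna))),
        sourceIntervals = iv)
  })
}

#' Construct a RegionSequence from a plain string
#'
#' Convenience constructor for scanning ad-hoc sequences (probes,
#' fixtures) with the region-based API; source intervals are set to the
#' trivial region-local interval.
#'
#' @param sequence RNA string (T is converted to U).
#' @param transcriptId identifier (default `"query"`).
#' @param region region label (default `"FULL"`).
#' @return a [RegionSequence-class].
#' @export
regionSeq <- function(sequence, transcriptId = "query", region = "FULL") {
  s <- .dnaToRna(toupper(as.character(sequence)))
  n <- nchar(s)
  new("RegionSequence", transcriptId = as.character(transcriptId),
      region = .checkRegionLabel(region), sequence = RNAString(s),
      sourceIntervals = if (n) IRanges(1L, n) else IRanges())
}

#' Write region sequences to FASTA / tabulate a region index
#'
#' `writeRegions()` writes a flat list of [RegionSequence-class] objects
#' as RNA FASTA with headers `<transcript_id>|<region>`;
#' `readRegions()` reads such a file back (source intervals are
#' region-local after a round trip). `regionIndex()` tabulates
#' transcript, region and length, and optionally writes it as TSV.
#'
#' @param regions flat list of [RegionSequence-class] objects.
#' @param path output (input) file.
#' @return `writeRegions()`: `path`, invisibly. `readRegions()`: list of
#'   [RegionSequence-class]. `regionIndex()`: a `data.frame`.
#' @export
writeRegions <- function(regions, path) {
  seqs <- RNAStringSet(vapply(regions, function(r)
    as.character(r@sequence), character(1)))
  names(seqs) <- vapply(regions, function(r)
    paste0(r@transcriptId, "|", r@region), character(1))
  writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  if (!file.exists(path)) stop("region FASTA not found: ", path)
  seqs <- readRNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    parts <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("region FASTA header must be '<transcript_id>|<region>', got '",
           names(seqs)[i], "'")
    }
    n <- length(seqs[[i]])
    new("RegionSequence", transcriptId = parts[1L],
        region = .checkRegionLabel(parts[2L]), sequence = seqs[[i]],
        sourceIntervals = if (n) IRanges(1L, n) else IRanges())
  })
}

#' @param file optional TSV output path for `regionIndex()`.
#' @rdname writeRegions
#' @export
regionIndex <- function(regions, file = NULL) {
  idx <- data.frame(
    transcript_id = vapply(regions, transcriptId, character(1)),
    region = vapply(regions, regionLabel, character(1)),
    length = vapply(regions, length, integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(idx, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  idx
}

# Collapse isoforms to the one with the longest 3'UTR per gene.
.collapsePerGene <- function(models, genome) {
  genes <- vapply(models, geneId, character(1))
  u3len <- vapply(models, function(m) {
    sum(BiocGenerics::width(.regionGenomicIntervals(m)$THREE_UTR))
  }, numeric(1))
  keep <- unlist(lapply(split(seq_along(models), genes), function(idx) {
    idx[which.max(u3len[idx])]
  }), use.names = FALSE)
  models[sort(keep)]
}
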