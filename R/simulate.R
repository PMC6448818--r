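#' Configure the synthetic transcriptome generator
#'
#' Defaults describe a compact but structurally realistic transcriptome:
#' 60 multi-exon transcripts with 5'UTRs of 100-200 nt, CDS of 300-600
#' nt and 3'UTRs of 200-400 nt, 2-4 exons with UTRs split across exon
#' boundaries (so region stitching is always exercised), uniform
#' order-0 background, introns of 30-80 nt and 100-nt intergenic
#' spacers. Planting is off by default; set `plantRate` per region to
#' plant Poisson-distributed counts of `plantSequence`, optionally
#' mutated per position at `mutationRate`.
#'
#' @param nTranscripts number of transcripts.
#' @param exonCountRange `c(min, max)` exons per transcript.
#' @param fiveUtrRange,cdsRange,threeUtrRange region length ranges (nt).
#' @param background order-0 composition (A, C, G, U), default uniform.
#' @param transitions optional 4x4 first-order Markov transition matrix;
#'   when supplied, `background` seeds the first base of each segment.
#' @param plantRate expected planted instances per region: either a
#'   single number applied to `THREE_UTR` or a named vector over
#'   `FIVE_UTR`, `CDS`, `THREE_UTR`.
#' @param mutationRate per-position substitution probability for
#'   planted instances.
#' @param plantSequence RNA string to plant (default: native D3U-box
#'   core `CUGCUGCAGGU`).
#' @param intronRange intron length range (nt).
#' @param spacerLength intergenic spacer (nt).
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nTranscripts = 60L,
                      exonCountRange = c(2L, 4L),
                      fiveUtrRange = c(100L, 200L),
                      cdsRange = c(300L, 600L),
                      threeUtrRange = c(200L, 400L),
                      background = rep(0.25, 4),
                      transitions = NULL,
                      plantRate = 0,
                      mutationRate = 0,
                      plantSequence = "CUGCUGCAGGU",
                      intronRange = c(30L, 80L),
                      spacerLength = 100L,
                      seed = 1L) {
  if (length(plantRate) == 1L && is.null(names(plantRate))) {
    plantRate <- c(FIVE_UTR = 0, CDS = 0, THREE_UTR = unname(plantRate))
  } else {
    full <- c(FIVE_UTR = 0, CDS = 0, THREE_UTR = 0)
    full[names(plantRate)] <- plantRate
    plantRate <- full
  }
  if (is.null(transitions)) transitions <- matrix(numeric(0), 0L, 0L)
  new("SimConfig",
      nTranscripts = as.integer(nTranscripts),
      exonCountRange = as.integer(exonCountRange),
      fiveUtrRange = as.integer(fiveUtrRange),
      cdsRange = as.integer(cdsRange),
      threeUtrRange = as.integer(threeUtrRange),
      background = background / sum(background),
      transitions = transitions,
      plantRate = plantRate,
      mutationRate = mutationRate,
      plantSequence = toupper(plantSequence),
      intronRange = as.integer(intronRange),
      spacerLength = as.integer(spacerLength),
      seed = as.integer(seed))
}

# Safe uniform draw from an explicit candidate vector (avoids the
# base-R sample() scalar pitfall when the vector has length 1).
.sampleFrom <- function(v, n = 1L, replace = FALSE) {
  v[sample.int(length(v), n, replace = replace)]
}

# Sample n background bases (RNA letters) under order-0 or order-1.
.sampleBackground <- function(n, config) {
  if (n == 0L) return(character(0))
  if (nrow(config@transitions) == 0L) {
    RNA_BASES[sample.int(4L, n, replace = TRUE, prob = config@background)]
  } else {
    cum <- t(apply(config@transitions, 1L, cumsum))
    u <- runif(n)
    st <- integer(n)
    st[1L] <- sample.int(4L, 1L, prob = config@background)
    for (i in seq_len(n - 1L)) {
      st[i + 1L] <- findInterval(u[i + 1L], cum[st[i], ],
                                 left.open = TRUE) + 1L
    }
    RNA_BASES[st]
  }
}

# Non-overlapping 0-based plant offsets in a region of length m for
# nInst instances of width w; rejection sampling, capped retries.
.plantOffsets <- function(m, nInst, w) {
  placed <- integer(0)
  for (k in seq_len(nInst)) {
    for (try in seq_len(100L)) {
      o <- sample.int(m - w + 1L, 1L) - 1L
      if (!length(placed) ||
          all(o + w <= placed | o >= placed + w)) {
        placed <- c(placed, o)
        break
      }
    }
  }
  sort(placed)
}

# Exon cut points (transcript coordinates, cut after position c) chosen
# so UTRs are split across exons whenever the exon count allows: the
# last cut falls inside the 3'UTR, and with >= 3 exons the first cut
# falls inside the 5'UTR; remaining cuts land in the CDS.
.chooseCuts <- function(l5, lc, l3, k) {
  if (k == 1L) return(integer(0))
  total <- l5 + lc + l3
  cut3 <- .sampleFrom((total - l3 + 1L):(total - 1L))
  if (k == 2L) return(cut3)
  cut5 <- .sampleFrom(seq_len(l5 - 1L))
  nMid <- k - 3L
  mid <- if (nMid > 0L) {
    .sampleFrom((l5 + 1L):(l5 + lc - 1L), nMid)
  } else {
    integer(0)
  }
  sort(c(cut5, mid, cut3))
}

#' Simulate a transcriptome with planted motif instances
#'
#' Generates a single-contig genome carrying `nTranscripts` gene models
#' with known region structure, a matching annotation, and a truth
#' table of planted motif instances. Per transcript: region lengths and
#' exon count are drawn from the configured ranges; planted instance
#' counts are Poisson(`plantRate`) per region, placed uniformly without
#' overlap (rejection sampling with capped retries) and mutated per
#' position at `mutationRate`; exon boundaries are placed so that UTRs
#' span exons (stitching is always exercised); strands are random.
#' Accidental background occurrences of the motif are not removed.
#' Fully deterministic given `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `models`
#'   (named list of [TranscriptModel-class]), `regions` (flat list of
#'   the generated [RegionSequence-class] objects, the ground truth the
#'   extractor must reproduce), `truth` (a `data.frame` with columns
#'   `transcript_id`, `region`, `offset`, `planted_sequence`,
#'   `n_mutations`) and `config`.
#' @seealso [writeSimulation()], [recoveryReport()]
#' @export
simulateTranscriptome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  w <- nchar(config@plantSequence)
  for (lab in names(config@plantRate)) {
    minLen <- switch(lab, FIVE_UTR = config@fiveUtrRange[1L],
                     CDS = config@cdsRange[1L],
                     THREE_UTR = config@threeUtrRange[1L])
    if (config@plantRate[[lab]] > 0 && minLen < w) {
      stop("region ", lab, " (min length ", minLen,
           ") is too short for a planted instance of length ", w)
    }
  }
  .withSeed(config@seed, .simulateImpl(config, w))
}

.simulateImpl <- function(config, w) {
  plantChars <- strsplit(config@plantSequence, "")[[1L]]
  contigParts <- character(0)
  pos <- 0L  # bases emitted so far on the contig
  models <- vector("list", config@nTranscripts)
  regions <- vector("list", 4L * config@nTranscripts)
  truth <- list()

  for (t in seq_len(config@nTranscripts)) {
    tid <- sprintf("tx%04d", t)
    gid <- sprintf("gene%04d", t)
    l5 <- .sampleFrom(config@fiveUtrRange[1L]:config@fiveUtrRange[2L])
    lc <- .sampleFrom(config@cdsRange[1L]:config@cdsRange[2L])
    l3 <- .sampleFrom(config@threeUtrRange[1L]:config@threeUtrRange[2L])
    k <- .sampleFrom(config@exonCountRange[1L]:config@exonCountRange[2L])
    total <- l5 + lc + l3
    std <- sample(c("+", "-"), 1L)

    full <- .sampleBackground(total, config)
    regionStart0 <- c(FIVE_UTR = 0L, CDS = l5, THREE_UTR = l5 + lc)
    regionLen <- c(FIVE_UTR = l5, CDS = lc, THREE_UTR = l3)
    for (lab in names(config@plantRate)) {
      rate <- config@plantRate[[lab]]
      if (rate <= 0) next
      nInst <- rpois(1L, rate)
      if (nInst == 0L) next
      offs <- .plantOffsets(regionLen[[lab]], nInst, w)
      for (o in offs) {
        inst <- plantChars
        nMut <- 0L
        if (config@mutationRate > 0) {
          mutate <- runif(w) < config@mutationRate
          nMut <- sum(mutate)
          for (j in which(mutate)) {
            inst[j] <- sample(setdiff(RNA_BASES, inst[j]), 1L)
          }
        }
        g0 <- regionStart0[[lab]] + o
        full[(g0 + 1L):(g0 + w)] <- inst
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = tid, region = lab, offset = o,
          planted_sequence = paste(inst, collapse = ""),
          n_mutations = nMut, stringsAsFactors = FALSE
        )
      }
    }

    fullStr <- paste(full, collapse = "")
    cuts <- .chooseCuts(l5, lc, l3, k)
    bounds <- c(0L, cuts, total)
    exTx <- .fastIRanges(bounds[-length(bounds)] + 1L, bounds[-1L])

    # transcript-order layout within the local genomic segment
    nEx <- length(exTx)
    intronLens <- if (nEx > 1L) {
      .sampleFrom(config@intronRange[1L]:config@intronRange[2L],
                  nEx - 1L, replace = TRUE)
    } else {
      integer(0)
    }
    segParts <- character(0)
    layoutStart <- integer(nEx)
    cursor <- 0L
    for (j in seq_len(nEx)) {
      layoutStart[j] <- cursor + 1L
      exSeq <- substr(fullStr, BiocGenerics::start(exTx)[j],
                      BiocGenerics::end(exTx)[j])
      segParts <- c(segParts, exSeq)
      cursor <- cursor + nchar(exSeq)
      if (j < nEx) {
        intr <- paste(.sampleBackground(intronLens[j], config),
                      collapse = "")
        segParts <- c(segParts, intr)
        cursor <- cursor + intronLens[j]
      }
    }
    segRna <- paste(segParts, collapse = "")
    segLen <- nchar(segRna)
    segDna <- .rnaToDna(segRna)
    if (std == "-") {
      segDna <- as.character(reverseComplement(DNAString(segDna)))
    }

    # map a transcript-layout interval to local genomic coordinates
    mapLocal <- function(s, e) {
      if (std == "+") c(s, e) else c(segLen - e + 1L, segLen - s + 1L)
    }
    exLocal <- t(vapply(seq_len(nEx), function(j) {
      mapLocal(layoutStart[j],
               layoutStart[j] + BiocGenerics::width(exTx)[j] - 1L)
    }, integer(2)))

    # transcript position -> layout position
    txToLayout <- function(p) {
      j <- findInterval(p, BiocGenerics::start(exTx))
      layoutStart[j] + (p - BiocGenerics::start(exTx)[j])
    }
    cdsLocal <- sort(c(mapLocal(txToLayout(l5 + 1L), txToLayout(l5 + 1L))[1L],
                       mapLocal(txToLayout(l5 + lc), txToLayout(l5 + lc))[1L]))

    spacer <- paste(.rnaToDna(.sampleBackground(config@spacerLength, config)),
                    collapse = "")
    contigParts <- c(contigParts, spacer, segDna)
    offset <- pos + config@spacerLength
    pos <- offset + segLen

    exAbs <- .fastIRanges(offset + exLocal[, 1L], offset + exLocal[, 2L])
    cdsAbs <- .fastIRanges(offset + cdsLocal[1L], offset + cdsLocal[2L])
    models[[t]] <- TranscriptModel(tid, gid, "simchr1", std,
                                   exAbs[order(BiocGenerics::start(exAbs))],
                                   cdsAbs)

    # objects are internally consistent by construction; skip the
    # (per-object costly) validity machinery in this hot loop
    mk <- function(lab, s0, len) {
      S4Vectors::new2("RegionSequence", transcriptId = tid, region = lab,
                      sequence = RNAString(substr(fullStr, s0 + 1L,
                                                  s0 + len)),
                      sourceIntervals = if (len) .fastIRanges(1L, len)
                        else IRanges(),
                      check = FALSE)
    }
    regions[[4L * (t - 1L) + 1L]] <- mk("FIVE_UTR", 0L, l5)
    regions[[4L * (t - 1L) + 2L]] <- mk("CDS", l5, lc)
    regions[[4L * (t - 1L) + 3L]] <- mk("THREE_UTR", l5 + lc, l3)
    regions[[4L * (t - 1L) + 4L]] <- mk("FULL", 0L, total)
  }
  contigParts <- c(contigParts,
                   paste(.rnaToDna(.sampleBackground(config@spacerLength,
                                                     config)),
                         collapse = ""))
  genome <- DNAStringSet(setNames(paste(contigParts, collapse = ""),
                                  "simchr1"))
  names(models) <- vapply(models, transcriptId, character(1))
  truthDf <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(transcript_id = character(0), region = character(0),
               offset = integer(0), planted_sequence = character(0),
               n_mutations = integer(0), stringsAsFactors = FALSE)
  }
  list(genome = genome, models = models, regions = regions,
       truth = truthDf, config = config)
}

#' Write a simulation to FASTA + GFF3 + truth TSV
#'
#' Emits the genome FASTA, a GFF3 with explicit gene/mRNA/exon/CDS
#' features (UTRs are left implicit, exercising the parser's exon/CDS
#' derivation path), the truth table as TSV and the configuration as
#' JSON. Byte-identical across runs for the same simulation.
#'
#' @param sim result of [simulateTranscriptome()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "annotation.gff3"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  writeXStringSet(sim$genome, paths[["genome"]])
  export(.modelsToGff(sim$models), paths[["annotation"]], format = "gff3")
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  write_json(list(
    n_transcripts = cfg@nTranscripts, exon_count_range = cfg@exonCountRange,
    five_utr_range = cfg@fiveUtrRange, cds_range = cfg@cdsRange,
    three_utr_range = cfg@threeUtrRange, background = cfg@background,
    plant_rate = as.list(cfg@plantRate), mutation_rate = cfg@mutationRate,
    plant_sequence = cfg@plantSequence, intron_range = cfg@intronRange,
    spacer_length = cfg@spacerLength, seed = cfg@seed
  ), paths[["config"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# GRanges with gene/mRNA/exon/CDS rows and GFF3 ID/Parent attributes.
.modelsToGff <- function(models) {
  rows <- lapply(models, function(m) {
    ex <- m@exons
    span <- range(c(BiocGenerics::start(ex), BiocGenerics::end(ex)))
    n <- 2L + length(ex)
    starts <- c(span[1L], span[1L], BiocGenerics::start(ex))
    ends <- c(span[2L], span[2L], BiocGenerics::end(ex))
    types <- c("gene", "mRNA", rep("exon", length(ex)))
    ids <- c(m@geneId, m@transcriptId, rep(NA_character_, length(ex)))
    parents <- c(NA_character_, m@geneId,
                 rep(m@transcriptId, length(ex)))
    phases <- rep(NA_integer_, n)
    if (length(m@cdsSpan)) {
      lo <- BiocGenerics::start(m@cdsSpan)
      hi <- BiocGenerics::end(m@cdsSpan)
      cs <- pmax(BiocGenerics::start(ex), lo)
      ce <- pmin(BiocGenerics::end(ex), hi)
      keep <- cs <= ce
      cs <- cs[keep]; ce <- ce[keep]
      # phase per CDS piece, in translation (transcript) order
      ord <- if (m@strand == "+") order(cs) else order(-cs)
      lens <- (ce - cs + 1L)[ord]
      ph <- integer(length(lens))
      if (length(lens) > 1L) {
        before <- cumsum(lens)[-length(lens)]
        ph[-1L] <- (3L - before %% 3L) %% 3L
      }
      phase <- integer(length(lens))
      phase[ord] <- ph
      starts <- c(starts, cs)
      ends <- c(ends, ce)
      types <- c(types, rep("CDS", length(cs)))
      ids <- c(ids, rep(NA_character_, length(cs)))
      parents <- c(parents, rep(m@transcriptId, length(cs)))
      phases <- c(phases, phase)
    }
    data.frame(start = starts, end = ends, type = types, ID = ids,
               Parent = parents, phase = phases,
               strand = m@strand, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GRanges("simchr1", IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$type <- df$type
  mcols(gr)$ID <- df$ID
  parentList <- lapply(df$Parent, function(p) if (is.na(p)) character(0) else p)
  mcols(gr)$Parent <- IRanges::CharacterList(parentList)
  mcols(gr)$phase <- df$phase
  gr
}

#' Score planted-motif recovery of a hit list
#'
#' A planted instance counts as recovered when a hit of the same
#' transcript and region overlaps it after expanding the planted
#' interval by `matchWindow` nt on both sides. Sensitivity is
#' `recovered / planted`; precision is `truth-matched hits / all hits`
#' (`NA` when there are no hits). Background (non-planted) occurrences
#' of the motif count against precision by design.
#'
#' @param hits hit `data.frame` from [scanRegion()]/[scanRegions()].
#' @param truth truth `data.frame` from [simulateTranscriptome()].
#' @param matchWindow slack in nt (default 0: direct overlap).
#' @return list with `sensitivity`, `precision`, `nPlanted`,
#'   `nRecovered`, `nHits` and `perRegion` (a confusion `data.frame`
#'   with planted / recovered / hits / matched hits per region class).
#' @export
recoveryReport <- function(hits, truth, matchWindow = 0L) {
  if (nrow(hits) && nrow(truth) &&
      !any(hits$transcript_id %in% truth$transcript_id)) {
    stop("hit and truth tables share no transcript identifiers; ",
         "are they from the same simulation?")
  }
  truthEnd <- truth$offset + nchar(truth$planted_sequence)  # half-open
  recovered <- logical(nrow(truth))
  hitMatched <- logical(nrow(hits))
  if (nrow(hits) && nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      cand <- hits$transcript_id == truth$transcript_id[i] &
        hits$region == truth$region[i] &
        hits$offset < truthEnd[i] + matchWindow &
        hits$end > truth$offset[i] - matchWindow
      if (any(cand)) {
        recovered[i] <- TRUE
        hitMatched[cand] <- TRUE
      }
    }
  }
  perRegion <- do.call(rbind, lapply(c("FIVE_UTR", "CDS", "THREE_UTR"),
                                     function(lab) {
    tsel <- truth$region == lab
    hsel <- hits$region == lab
    data.frame(region = lab, planted = sum(tsel),
               recovered = sum(recovered[tsel]), hits = sum(hsel),
               matched_hits = sum(hitMatched[hsel]),
               stringsAsFactors = FALSE)
  }))
  list(
    sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
    precision = if (nrow(hits)) mean(hitMatched) else NA_real_,
    nPlanted = nrow(truth), nRecovered = sum(recovered),
    nHits = nrow(hits), perRegion = perRegion
  )
}
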