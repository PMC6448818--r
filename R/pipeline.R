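# Minimal --flag value parser for the subcommand interface. Flags with
# no following value (or followed by another flag) are treated as
# logical switches.
.parseArgs <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

.need <- function(opts, key, sub) {
  val <- opts[[key]]
  if (is.null(val) || isTRUE(val)) {
    stop("subcommand '", sub, "' requires --", key, " <value>")
  }
  val
}

.checkInput <- function(path, what) {
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

.log <- function(level, ...) {
  message("[", level, "] ", ...)
}

# Record inputs (with md5), parameters and seed next to the outputs so
# a deterministic stage can be re-executed bit-identically.
.writeManifest <- function(dir, subcommand, inputs, parameters,
                           seed = NULL) {
  manifest <- list(
    subcommand = subcommand,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = parameters,
    seed = seed,
    tool_version = as.character(utils::packageVersion("utrmotif")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, paste0("manifest_", subcommand, ".json"))
  write_json(manifest, path, auto_unbox = TRUE, digits = NA,
             pretty = TRUE, null = "null")
  invisible(path)
}

.scanParamsFromOpts <- function(opts) {
  scanParams(
    mode = if (is.null(opts[["mode"]])) "iupac" else opts[["mode"]],
    pwmThreshold = if (is.null(opts[["threshold"]])) 0.8 else
      as.numeric(opts[["threshold"]]),
    thresholdType = if (is.null(opts[["threshold-type"]])) "fraction" else
      opts[["threshold-type"]],
    maxMismatch = if (is.null(opts[["max-mismatch"]])) 0L else
      as.integer(opts[["max-mismatch"]]),
    nPolicy = if (is.null(opts[["n-policy"]])) "reject_window" else
      opts[["n-policy"]]
  )
}

#' Run a pipeline stage from command-line-style arguments
#'
#' Dispatches the stage subcommands (`simulate`, `build-matrix`,
#' `extract`, `scan`, `scan-split`, `enrich`, `profile`, `recover`)
#' over the package's functions, writing stage outputs as
#' FASTA/GFF3/TSV plus a JSON run manifest (inputs with content hashes,
#' parameters, seed, tool version). Stages communicate through files,
#' so each one can be tested against fixtures in isolation; no
#' subcommand mutates its inputs. A thin Rscript wrapper around this
#' function ships in `inst/scripts/utrmotif`.
#'
#' @param args character vector, e.g.
#'   `c("scan", "--matrix", "m.txt", "--regions", "r.fasta", "--mode",
#'   "exact", "--out-dir", "out")`.
#' @return invisibly, a named list of output paths.
#' @export
runPipeline <- function(args) {
  if (!length(args)) {
    stop("usage: utrmotif <simulate|build-matrix|extract|scan|scan-split|",
         "enrich|profile|recover> [--flags]")
  }
  sub <- args[1L]
  opts <- .parseArgs(args[-1L])
  outDir <- if (is.null(opts[["out-dir"]])) "." else opts[["out-dir"]]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dispatch <- switch(sub,
    "simulate" = .cmdSimulate,
    "build-matrix" = .cmdBuildMatrix,
    "extract" = .cmdExtract,
    "scan" = .cmdScan,
    "scan-split" = .cmdScanSplit,
    "enrich" = .cmdEnrich,
    "profile" = .cmdProfile,
    "recover" = .cmdRecover,
    stop("unknown subcommand '", sub, "'")
  )
  .log("INFO", "running subcommand '", sub, "'")
  out <- dispatch(opts, outDir)
  .log("INFO", "subcommand '", sub, "' finished")
  invisible(out)
}

.cmdSimulate <- function(opts, outDir) {
  seed <- as.integer(.need(opts, "seed", "simulate"))
  cfgArgs <- list(seed = seed)
  if (!is.null(opts[["config"]])) {
    .checkInput(opts[["config"]], "config file")
    cj <- read_json(opts[["config"]], simplifyVector = TRUE)
    map <- c(n_transcripts = "nTranscripts",
             exon_count_range = "exonCountRange",
             five_utr_range = "fiveUtrRange", cds_range = "cdsRange",
             three_utr_range = "threeUtrRange", background = "background",
             plant_rate = "plantRate", mutation_rate = "mutationRate",
             plant_sequence = "plantSequence", intron_range = "intronRange",
             spacer_length = "spacerLength")
    for (key in intersect(names(cj), names(map))) {
      val <- cj[[key]]
      if (key == "plant_rate" && is.list(val)) val <- unlist(val)
      cfgArgs[[map[[key]]]] <- val
    }
  }
  config <- do.call(simConfig, cfgArgs)
  sim <- simulateTranscriptome(config)
  paths <- writeSimulation(sim, outDir)
  regPath <- file.path(outDir, "regions.fasta")
  writeRegions(sim$regions, regPath)
  .writeManifest(outDir, "simulate",
                 inputs = if (is.null(opts[["config"]])) list() else
                   list(config = opts[["config"]]),
                 parameters = list(n_transcripts = config@nTranscripts),
                 seed = seed)
  c(paths, regions = regPath)
}

.cmdBuildMatrix <- function(opts, outDir) {
  inst <- .checkInput(.need(opts, "instances", "build-matrix"),
                      "instance file")
  pc <- if (is.null(opts[["pseudocount"]])) 0.25 else
    as.numeric(opts[["pseudocount"]])
  m <- buildMatrix(readMotifInstances(inst), pseudocount = pc,
                   name = if (is.null(opts[["name"]])) "motif" else opts[["name"]])
  out <- file.path(outDir, "matrix.txt")
  writeMotifMatrix(m, out)
  .writeManifest(outDir, "build-matrix", list(instances = inst),
                 list(pseudocount = pc, consensus = consensusIupac(m)))
  c(matrix = out)
}

.cmdExtract <- function(opts, outDir) {
  gf <- .checkInput(.need(opts, "genome", "extract"), "genome FASTA")
  af <- .checkInput(.need(opts, "gff", "extract"), "annotation")
  dialect <- if (is.null(opts[["dialect"]])) "gff3" else opts[["dialect"]]
  genome <- readGenome(gf)
  models <- readAnnotation(af, dialect = dialect)
  if (isTRUE(opts[["per-gene"]])) {
    models <- .collapsePerGene(models, genome)
  }
  regions <- unlist(lapply(models, extractRegions, genome = genome),
                    recursive = FALSE, use.names = FALSE)
  fa <- file.path(outDir, "regions.fasta")
  writeRegions(regions, fa)
  idx <- file.path(outDir, "region_index.tsv")
  regionIndex(regions, idx)
  .writeManifest(outDir, "extract", list(genome = gf, gff = af),
                 list(dialect = dialect,
                      per_gene = isTRUE(opts[["per-gene"]]),
                      n_transcripts = length(models)))
  c(regions = fa, index = idx)
}

.cmdScan <- function(opts, outDir) {
  mf <- .checkInput(.need(opts, "matrix", "scan"), "matrix file")
  rf <- .checkInput(.need(opts, "regions", "scan"), "region FASTA")
  params <- .scanParamsFromOpts(opts)
  m <- readMotifMatrix(mf)
  regions <- readRegions(rf)
  hits <- scanRegions(m, regions, params)
  out <- file.path(outDir, "hits.tsv")
  writeHits(hits, out)
  .writeManifest(outDir, "scan", list(matrix = mf, regions = rf),
                 list(mode = params@mode, n_hits = nrow(hits)))
  c(hits = out)
}

.cmdScanSplit <- function(opts, outDir) {
  mf <- .checkInput(.need(opts, "matrix", "scan-split"), "matrix file")
  rf <- .checkInput(.need(opts, "regions", "scan-split"), "region FASTA")
  params <- .scanParamsFromOpts(opts)
  splitIdx <- if (is.null(opts[["split-index"]])) 6L else
    as.integer(opts[["split-index"]])
  minGap <- if (is.null(opts[["min-gap"]])) 0L else
    as.integer(opts[["min-gap"]])
  maxGap <- if (is.null(opts[["max-gap"]])) 10L else
    as.integer(opts[["max-gap"]])
  sm <- splitMotif(readMotifMatrix(mf), splitIdx, minGap, maxGap)
  regions <- readRegions(rf)
  pairs <- do.call(rbind, lapply(regions, function(r) {
    scanSplit(sm, r, params)$pairs
  }))
  out <- file.path(outDir, "split_pairs.tsv")
  utils::write.table(pairs, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .writeManifest(outDir, "scan-split", list(matrix = mf, regions = rf),
                 list(split_index = splitIdx, min_gap = minGap,
                      max_gap = maxGap, n_pairs = nrow(pairs)))
  c(pairs = out)
}

.cmdEnrich <- function(opts, outDir) {
  mf <- .checkInput(.need(opts, "matrix", "enrich"), "matrix file")
  rf <- .checkInput(.need(opts, "regions", "enrich"), "region FASTA")
  seed <- as.integer(.need(opts, "seed", "enrich"))
  nControls <- if (is.null(opts[["n-controls"]])) 99L else
    as.integer(opts[["n-controls"]])
  counting <- if (is.null(opts[["counting"]])) "transcripts_with_hit" else
    opts[["counting"]]
  lab <- if (is.null(opts[["region"]])) "THREE_UTR" else opts[["region"]]
  params <- .scanParamsFromOpts(opts)
  m <- readMotifMatrix(mf)
  regions <- readRegions(rf)
  regions <- regions[vapply(regions, regionLabel, character(1)) == lab]
  res <- enrichmentTest(m, scrambleControls(m, nControls, seed), regions,
                        params, counting)
  out <- file.path(outDir, "enrichment.tsv")
  utils::write.table(as.data.frame(res), out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .writeManifest(outDir, "enrich", list(matrix = mf, regions = rf),
                 list(region = lab, n_controls = nControls,
                      counting = counting, mode = params@mode),
                 seed = seed)
  c(enrichment = out)
}

.cmdProfile <- function(opts, outDir) {
  mf <- .checkInput(.need(opts, "matrix", "profile"), "matrix file")
  rf <- .checkInput(.need(opts, "regions", "profile"), "region FASTA")
  seed <- as.integer(.need(opts, "seed", "profile"))
  nControls <- if (is.null(opts[["n-controls"]])) 99L else
    as.integer(opts[["n-controls"]])
  counting <- if (is.null(opts[["counting"]])) "transcripts_with_hit" else
    opts[["counting"]]
  params <- .scanParamsFromOpts(opts)
  out <- file.path(outDir, "region_profile.tsv")
  regionProfile(readMotifMatrix(mf), readRegions(rf), params,
                nControls, seed, counting, file = out)
  .writeManifest(outDir, "profile", list(matrix = mf, regions = rf),
                 list(n_controls = nControls, counting = counting,
                      mode = params@mode), seed = seed)
  c(profile = out)
}

.cmdRecover <- function(opts, outDir) {
  hf <- .checkInput(.need(opts, "hits", "recover"), "hit table")
  tf <- .checkInput(.need(opts, "truth", "recover"), "truth table")
  mw <- if (is.null(opts[["match-window"]])) 0L else
    as.integer(opts[["match-window"]])
  hits <- utils::read.table(hf, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  names(hits)[names(hits) == "offset_0based"] <- "offset"
  truth <- utils::read.table(tf, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  rep <- recoveryReport(hits, truth, mw)
  out <- file.path(outDir, "recovery.json")
  write_json(list(sensitivity = rep$sensitivity,
                  precision = rep$precision, n_planted = rep$nPlanted,
                  n_recovered = rep$nRecovered, n_hits = rep$nHits),
             out, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(rep$perRegion,
                     file.path(outDir, "recovery_per_region.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "recover", list(hits = hf, truth = tf),
                 list(match_window = mw))
  c(recovery = out)
}
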