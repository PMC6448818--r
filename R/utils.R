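# Internal helpers shared across modules. RNA alphabet order is fixed
# (A < C < G < U) throughout; integer codes 1..4, N = 5.

RNA_BASES <- c("A", "C", "G", "U")

# IUPAC degeneracy codes over the RNA alphabet.
IUPAC_EXPAND <- c(
  A = "A", C = "C", G = "G", U = "U",
  M = "AC", R = "AG", W = "AU", S = "CG", Y = "CU", K = "GU",
  V = "ACG", H = "ACU", D = "AGU", B = "CGU", N = "ACGU"
)

# sorted-letter-set -> code, e.g. "CG" -> "S"
IUPAC_FROM_SET <- local({
  keys <- vapply(strsplit(IUPAC_EXPAND, ""),
                 function(x) paste(sort(x), collapse = ""), character(1))
  stats::setNames(names(IUPAC_EXPAND), keys)
})

# Encode an RNA string as integer codes A=1 C=2 G=3 U=4 N=5.
.encodeRNA <- function(x) {
  codes <- utf8ToInt(chartr("ACGUN", "\1\2\3\4\5", x))
  if (length(codes) && any(codes > 5L)) {
    bad <- which(codes > 5L)[1L]
    stop("illegal RNA character '", substr(x, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  codes
}

.decodeRNA <- function(codes) {
  paste(c(RNA_BASES, "N")[codes], collapse = "")
}

.dnaToRna <- function(x) chartr("Tt", "Uu", x)
.rnaToDna <- function(x) chartr("Uu", "Tt", x)

# Hamming distance between equal-length strings.
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length for Hamming distance",
         call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

REGION_LABELS <- c("FIVE_UTR", "CDS", "THREE_UTR", "FULL")

# Bare IRanges constructor for hot loops: the exported IRanges() spends
# most of its time in metadata scaffolding we never use.
.fastIRanges <- function(start, end) {
  S4Vectors::new2("IRanges", start = as.integer(start),
                  width = as.integer(end - start + 1L), check = FALSE)
}

.checkRegionLabel <- function(region) {
  if (!region %in% REGION_LABELS) {
    stop("region must be one of ", paste(REGION_LABELS, collapse = ", "),
         call. = FALSE)
  }
  region
}

# Empty hit table; the single source of the hit-table column contract.
.emptyHits <- function() {
  data.frame(
    transcript_id = character(0), region = character(0),
    offset = integer(0), end = integer(0), matched = character(0),
    score = numeric(0), mismatches = integer(0),
    motif_name = character(0), stringsAsFactors = FALSE
  )
}
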