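---
title: "Scanning transcript regions for a bipartite 3'UTR element: models and methods"
author: "utrmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning transcript regions for a bipartite 3'UTR element}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrmotif)
```

## The problem

The D3U-box is an 11-nt cis-regulatory element (core `CUGCUGCAGGU`)
first described in the 3'UTR of the medaka master sex-determining gene
*dmrt1bY*, where it stabilises the transcript in primordial germ cells.
The element is bipartite: a CUG-repeat half recognised by a
CUG-binding (CELF-family) protein and a `CAGGU` half recognised by an
LRPPRC/BSF-family protein, two RNA-binding proteins with antagonistic
effects on transcript stability. Asking "which other transcripts carry
this element, and specifically in which region?" requires a pipeline
that can (i) represent the element quantitatively, (ii) extract
transcript regions — 5'UTR, CDS, 3'UTR — from a genome and its
annotation even when UTRs are spread across several exons, (iii) scan
those regions for full and split occurrences, and (iv) decide whether
the observed occurrence counts exceed what composition-matched null
motifs produce. `utrmotif` implements those four stages plus a
synthetic-transcriptome generator that makes every stage testable
without downloading any annotation.

## The motif model

A motif of length $L$ is a position count matrix over the RNA alphabet
$(A, C, G, U)$ built from aligned instances, smoothed with a per-cell
pseudocount $q$:

$$p_{i,x} = \frac{c_{i,x} + q}{n + 4q}.$$

The default $q = 0.25$ (one quarter of a pseudo-observation per letter)
keeps log-odds scores finite even for a single-instance indicator
matrix; $q = 0$ is available when exact counting is wanted. Scoring is
the standard summed log-odds against a background composition $b$:

$$S(w) = \sum_{i=1}^{L} \log_2 \frac{p_{i,w_i}}{b_{w_i}},$$

in bits. Only two core variants of the element are available as
machine-readable printed sequences (the native medaka core and the
olive-fruit-fly variant, which differ at one position); they ship in
`inst/extdata/` and are the default instance set. The full
cross-species alignment behind the published matrix exists only in
graphical form, so matrices built from richer instance sets can be
supplied by the user through the same interface; nothing in the
pipeline depends on the default.

Three scan modes cover the useful operating points:

* `exact` — match the single-letter consensus with zero mismatches
  (per-position argmax; ties broken by the fixed alphabet order
  A < C < G < U so results are deterministic).
* `iupac` — match the degenerate consensus (letters with
  $p_{i,x} \ge$ `minFrac`, default 0.5) allowing up to `maxMismatch`
  mismatching positions.
* `pwm` — keep windows with $S(w)$ at or above a threshold given
  either in bits or, by default, as a fraction of the matrix's maximum
  attainable score (default 0.8). The fractional form is what makes
  scrambled controls comparable: each permuted matrix is scanned
  against its own maximum.

Scanning is sense-strand only: the element acts at the RNA level
within transcribed sequence, so a reverse-complement scan would count
biologically meaningless antisense matches. Windows containing `N` are
rejected in `exact`/`iupac` modes; in `pwm` mode a policy slot chooses
between rejection (default, conservative for presence/absence
counting) and scoring `N` as 0 bits. All overlapping hits are
reported; collapsing is a counting-stage decision, not a scanner
decision.

## Split (bipartite) scanning

`splitMotif()` partitions the matrix into a 5' and a 3' half — by
default after position 6, separating `CUGCUG` from `CAGGU`, the two
protein-binding half-sites. The exact split coordinate between the two
halves is not dictated by the biology (the CUG-repeat and CAGGU
descriptions name the halves, not a base-precise boundary), so it is a
configurable parameter with 6|5 as the default. `scanSplit()` reports
ordered pairs in which the 3' half lies strictly downstream of the 5'
half with a gap inside `[minGap, maxGap]`; the default gap window of
0–10 nt generalises the intact element (gap 0) to "two independent
sites in local proximity" while remaining fully configurable. Half-only
hit lists are returned alongside for diagnostics, which is how a
CUG-destroyed variant is seen to retain its `CAGGU` half.

Hits can be graded against a reference consensus by Hamming distance:
0 = exact, 1 = high, 2 = moderate, $\ge 3$ = weak. These cut-offs are a
package convention that operationalises qualitative conservation
language; they are deliberately simple and exposed as data (the
distance is always returned alongside the grade).

## Region extraction

Annotation is read from GFF3 (or GTF via a dialect flag) into
per-transcript models: exons attached by `Parent` attributes, the CDS
span taken as first-to-last CDS base. UTRs are always *derived* from
exon/CDS geometry — the exonic sequence 5' (respectively 3') of the
CDS span in transcript orientation — because annotation dumps vary in
whether explicit UTR features are present; when such features do
appear they are used purely as a consistency check and any
disagreement is a hard error. UTR regions spread across several exons
are stitched per transcript; minus-strand models are
reverse-complemented; output is RNA (T→U) because the element and the
printed probes are RNA. Coordinates are 1-based inclusive at the GFF3
boundary and 0-based half-open internally and in hit tables.

Isoform handling is not dictated by any published convention, so the
default is per-transcript processing, with a `--per-gene` option that
collapses each gene to the isoform with the longest 3'UTR (the region
of interest). Length conservation —
$|5'UTR| + |CDS| + |3'UTR| = |FULL|$ — is enforced by construction and
property-tested.

## Enrichment against scrambled controls

The null for "is the element enriched in 3'UTRs?" is a set of
column-permuted (scrambled) versions of the motif matrix: permuting
positions preserves the column multiset, hence base composition and
total information content, making the controls composition-matched by
construction. The identity permutation is excluded. Letter-shuffled
consensus strings were deliberately not used: they do not preserve
composition in general (the published scrambled probe, for example,
changes the base composition relative to the native core), which would
confound composition effects with positional structure.

With observed count $o$ and control counts $c_1, \dots, c_K$ scanned
under identical parameters:

* fold enrichment $= o / \bar c$, with an undefined sentinel (`NA`)
  when $\bar c = 0$;
* empirical p-value $= (1 + \#\{c_k \ge o\}) / (1 + K)$, the standard
  add-one permutation form, never 0, with granularity $1/(1+K)$.

The default $K = 99$ gives p-granularity 0.01 at modest cost. Two
counting modes exist because a bar of "occurrences" can mean either:
`transcripts_with_hit` (default; the per-gene presence count behind
statements like "found in more than 250 3'UTRs of genes") and
`total_hits`. No parametric test is attached to the counts: the
empirical permutation p is assumption-light and is the package's
deliberate statistical choice where the original analysis showed raw
occurrence bars without a named test. When several target motifs are
profiled the package emits no multiple-testing correction — it is a
single-motif tool, and a Bonferroni note applies if users loop it.

## The synthetic transcriptome generator

`simulateTranscriptome()` generates the study conditions under which
the pipeline is validated: a single contig carrying (by default) 60
gene models with 5'UTRs of 100–200 nt, CDS of 300–600 nt, 3'UTRs of
200–400 nt, 2–4 exons, introns of 30–80 nt, 100-nt intergenic
spacers, random strands and an i.i.d. uniform background (a 4×4
first-order Markov transition matrix can be supplied instead). These
sizes are compact relative to vertebrate genomes but structurally
faithful where it matters: exon boundaries are always placed inside
the UTRs (the last cut inside the 3'UTR, and with ≥3 exons the first
cut inside the 5'UTR), so region stitching across exon junctions —
including planted elements straddling a junction — is exercised by
every simulated transcript.

Planting draws a Poisson count per region at the configured rate,
places instances uniformly without overlap (rejection sampling with
capped retries, so truth counts equal plantable counts), writes the
configured element (default: the native core), then applies
independent per-position substitutions at the configured mutation
rate. Accidental background occurrences of the consensus are *not*
removed: they are part of the realistic false-positive floor, and the
closed-form expectation $(n - L + 1) \prod_i b_{w_i}$ — about
$2.4 \times 10^{-4}$ exact 11-mer hits per kilobase of uniform
background — quantifies it. `recoveryReport()` scores hits against
truth by overlap (within an optional slack window): sensitivity is
recovered/planted, precision is truth-matched hits over all hits, and
background hits count against precision by design.

What the generator does *not* emulate: realistic intron length and
gene-density distributions, nucleotide composition heterogeneity along
real chromosomes (isochores, CpG islands), alternative isoforms, and
annotation errors. Passing tests on simulated data therefore
demonstrate algorithmic correctness — that the pipeline finds what is
there, at calibrated error rates — not that any particular genome-wide
count will be reproduced; such counts depend on the depth and quality
of the annotation used.

## Numerical and calibration choices

* **Problem sizes.** The shipped test suite and acceptance script use
  60-transcript transcriptomes (30 for the 20-seed region-specificity
  sweep, 100 for recovery runs), 200 calibration replicates with 99
  controls each, 10,000 one-kilobase regions for the background-rate
  check, and ≥1,000 randomized scanner/oracle trials. These sizes were
  chosen once as the package's validation conditions: large enough
  that every stochastic check has clear resolution (3-standard-error
  bands, p-granularity 0.01), small enough to run on a laptop.
* **Calibration scan settings.** Null calibration of the empirical p
  and the region profile use `pwm` mode with a permissive
  fraction-of-max threshold of 0.4. The reason is statistical, not
  cosmetic: with an exact 11-mer scan the null expectation per
  transcriptome is ~$10^{-2}$ hits, so observed and control counts are
  almost surely all zero, every empirical p is 1, and the calibration
  check would be vacuous. At threshold 0.4 the null count per
  60-transcript replicate is ≈35, counts are rarely tied, and the
  add-one p is informative. Under exchangeability of the target with
  its column permutations on i.i.d. background, the fraction of
  background-only runs with $p \le 0.05$ should sit near 0.05 (slightly
  below, because ties are counted conservatively); the suite checks the
  95% binomial band [0.02, 0.08] around 0.05 at 200 replicates.
* **Floating-point thresholds.** pwm hits use
  `score >= threshold - 1e-9` so that the consensus window always
  attains its own maximum under a fraction-1.0 threshold despite
  summation order. Probability-row and background sums are validated
  to 1e-9.
* **Ties and degeneracies.** Argmax ties in the single-letter
  consensus resolve by alphabet order (A < C < G < U); this makes
  `minFrac = 1` consensus extraction deterministic but lossy for tied
  columns, which is documented at the call site. A length-1 motif
  cannot be scrambled (no non-identity permutation) and is rejected.
* **Degenerate inputs.** Regions shorter than the motif return empty
  hit lists rather than errors; empty region sets count 0; a zero
  control mean yields the `NA` fold sentinel while p remains defined;
  an all-zero run returns p = 1.

## Limitations

* Hits are reported in region-local coordinates; back-projection
  through introns to genomic coordinates is out of scope.
* RNA secondary structure around hits (e.g. CUG-repeat hairpins) is
  not modelled.
* The default instance set contains the only two printed core
  variants; the resulting matrix is nearly an indicator matrix and is
  deliberately exposed as replaceable input rather than a claim about
  the full cross-species motif.
* De novo motif discovery and dinucleotide-preserving shuffles are
  non-goals; the scrambling null is a column permutation.

## A worked example

```{r example, eval = FALSE}
library(utrmotif)

# the four printed probe sequences and the element core
probes <- emsaProbes()
m <- buildMatrix("CUGCUGCAGGU", name = "d3u")
scanRegion(m, probes[["native_d3u"]], scanParams("exact"))

# a planted-motif simulation and its recovery
sim <- simulateTranscriptome(simConfig(nTranscripts = 60,
                                       plantRate = 1.0, seed = 1))
u3 <- Filter(function(r) regionLabel(r) == "THREE_UTR", sim$regions)
hits <- scanRegions(m, u3, scanParams("exact"))
recoveryReport(hits, sim$truth)$sensitivity

# region-wise enrichment against 99 scrambled controls
regionProfile(m, sim$regions, scanParams("pwm", pwmThreshold = 0.4),
              nControls = 99, seed = 1, countingMode = "total_hits")
```
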