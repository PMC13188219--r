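---
title: "Locating sequenced 16S hypervariable regions: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating sequenced 16S hypervariable regions: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public archives hold millions of 16S rRNA metabarcoding runs whose technical
metadata — which hypervariable regions (V1–V9) were amplified, with which
primers, and whether the primers were trimmed — is missing, vague, or wrong.
That information decides how the raw reads must be processed (merging
parameters, truncation lengths, comparability across studies), so a curator
assembling a cross-study dataset has to recover it from the sequence data
itself. `hvrscan` does exactly that: given a sample's reads it reports where
on the *E. coli* 16S coordinate system the amplicon starts and ends, which
V-regions it covers, and whether primer sequences are likely still present.

## The coordinate model

All positions are expressed on a single reference 16S gene, 0-based and
inclusive, so a 1,541-base gene spans positions 0–1540. Region identity is
decided entirely by a nine-row boundary table (`load_region_map()`), shipped
as a TSV and trivially replaceable. The default table is the widely used
*E. coli* boundary convention (V1 = 68–98 … V9 = 1434–1464 after 0-based
conversion). Published boundary tables differ by a few bases between
sources; because every region call flows through the table, swapping
conventions is a data change, not a code change.

Two mapping rules translate a position into a region:

* **start rule** — the first region whose end is at or past the position.
  A position inside a region returns that region; a position in a conserved
  inter-region gap is attributed to the *next* region downstream, because an
  amplicon whose trimmed start sits in the conserved primer-binding stretch
  upstream of V*k* sequences V*k* first. This is what maps the canonical
  515F trim point, position 532, to V4.
* **end rule** — the mirror image: the last region whose start is at or
  before the position, so read-through into a conserved gap still reports
  the last variable region actually covered. Positions past V9 or before V1
  yield the sentinels `beyond-V9` / `before-V1` plus a warning, never an
  error, since 3' read-through beyond V9 occurs in real data.

Both mappings are monotone in the position; the asymmetry in the gaps is
intentional and is exercised directly by the tests.

### The bundled reference

The packaged reference (`synthetic_16s_reference.fasta`) is a **synthetic**
1,541-base stand-in for the *E. coli* gene: the conserved primer-binding
loci (27F, 338R/341F, 515F, 805R/806R, 926R, 1115F, 1492R) carry the real
conserved sequences at their canonical coordinates, while the variable
segments between them are seeded-random filler. Every coordinate-level
behaviour of the package — gene length 1541, maximum position 1540, primer
windows such as 515F–806R = 532–785 — is faithful to the real coordinate
system, and `load_reference()` accepts any single-record FASTA, so users
who want the GenBank record itself can point to it directly. What the
synthetic filler cannot provide is alignment of *real* taxonomically
diverse reads; see "What the simulator does and does not show" below.

## The pipeline

Per sample: take the first 1,000 reads (`n_reads`, the head of the stream,
matching how archived runs are spot-retrieved), quality-trim, merge mates
for paired layouts, align each processed sequence to the reference, then
summarize.

**Trimming.** A window (default 4 bases) slides in from the 3' end and the
tail is trimmed base-by-base while the window mean quality is below the
threshold (default Phred 15) *or* the terminal base itself is below it —
the guard means a kept read never ends in a sub-threshold base, so an
isolated good base cannot anchor a bad tail. Reads shorter than 50 bases
after trimming are discarded (a counted outcome). Trimming is provably
idempotent and never lengthens a read.

**Merging.** The reverse mate is reverse-complemented and all ungapped
suffix–prefix overlaps of at least 10 bases are scored matches − mismatches;
the best-scoring overlap is accepted if its mismatch fraction is ≤ 0.25
(score ties prefer the longer overlap, making self-merge an exact
identity). In the overlap the higher-quality base wins (ties keep the
forward base); consensus quality is the maximum of the two where the mates
agree and the minimum where they disagree. Indels inside the overlap are
not modelled — a deliberate simplification over fidelity, since merge
failures are merely counted toward the alignment-failure statistics and the
pairs involved are dropped rather than aligned as fragments (only the
merged path feeds the aligner).

**Alignment.** A semi-global (glocal) affine-gap dynamic program: the query
aligns end-to-end while reference positions before its first and after its
last base are free, which is the correct shape for locating a short
amplicon inside a full gene. Scores: match +2, mismatch −3, gap open −5,
gap extend −2 (a gap of length L costs 5 + 2L). Both orientations are
aligned and the higher score kept (ties keep forward), because archived
runs can be mixed-strand. A read counts as aligned only if (a) its score
is positive — an alignment no better than aligning nothing is noise —,
(b) identity over the aligned columns is ≥ 0.70, and (c) at least 50
columns align; failures define the "alignment error" class of warnings.
The thresholds are configurable (`scoring()`).

For speed, reads that share exact 13-mers with the reference are aligned
inside a diagonal band around their seed diagonals (±16 bases of indel
slack); reads that seed in neither orientation, and banded results that
fall under the identity bar, are re-aligned with the unrestricted DP, so
the band is an accelerator rather than a filter. The band is validated in
the test suite against the full DP, and the full DP in turn against an
independently written brute-force DP and against a second aligner
implementation.

**Summary and region calls.** Start/end statistics are computed over the
passing alignments; the median (middle value; mean of the two middle values
for even counts) drives the predicted regions through the mapping rules
above, because a handful of low-quality reads can skew the mean while
leaving the median untouched — both are reported, only the median decides.
The reported min/max columns are the *observed* minimum start and maximum
end in the sample (the theoretical bounds 0 and 1540 would carry no
per-sample information). Coverage at a position is the fraction of aligned
reads spanning it; per-region coverage is the mean over the region's
positions, and the coverage-based region calls are the lowest- and
highest-index regions reaching the threshold `t` (default 0.6), with NA and
a `LOW_COVERAGE` warning when none does.

**Failure taxonomy.** Samples are never silently dropped: rows carry
warning codes — `MISSING_FASTQ`, `NO_READS`, `LOW_READS` (fewer than 500
reads retrieved; the sample is failed and gets no region calls),
`HIGH_ALIGN_FAIL` (more than half of processed reads lost to merge or
alignment failure), `LOW_COVERAGE`, `BEYOND_V9`/`BEFORE_V1`, `READ_ERROR`
(malformed input). One sample's failure never affects another's row.

## Primer-presence detection

Untrimmed primers make the first sequencing cycles nearly base-identical
across reads, which leaves a recognisable signature in the quality-score
profile of those cycles. The classifier therefore sees only qualities,
never sequence: quality values at read positions 1–5 and 6–10 are pooled
across the first 1,000 reads (so the count statistic is about five times
the read count), and each segment is summarised by eight statistics —
count, mean, median, population standard deviation, minimum, maximum, and
the 25th and 75th percentiles (deliberately used as stand-ins for skewness
and kurtosis) — 16 features per sample in a fixed order. Quantiles use
linear interpolation (R type 7). Pooling across reads, rather than
summarising per read and averaging, is implied by "count" being a feature
at all.

A 100-tree random forest with a fixed seed (42) is trained on a labelled
corpus under a stratified 80/20 split, and held-out per-class precision and
recall ship with the model. The default model is trained deterministically
on first use from the simulated corpus (200 samples per class) and cached
for the session; `save_primer_model()`/`load_primer_model()` persist models
with their feature-order manifest, and the CLI exposes retraining on a
user-supplied corpus. Prediction reports both the TRUE/FALSE call at the
0.5 threshold and the underlying probability, so users can re-threshold.
Optional class weights exist for imbalanced corpora but are off by
default.

## What the simulator does and does not show

The generator (`simulate_sample()`) draws reads from a primer-trimmed
window of the reference — either an explicit window or a catalog entry
(six pairs including 515F–806R → V4/V4, 27F–338R → V1/V2,
341F–805R → V3/V4, with windows recomputed from the primer sequences and
frozen into a data file). Defaults: 1,000 reads per sample, i.i.d.
substitution errors at 1% per base, per-cycle Gaussian Phred qualities
(mean 34, sd 3, clamped to 2–41), fixed-length fragments (the whole window
for single-end; `read_len` prefix and reverse-complemented suffix for
pairs). With `with_primer = TRUE` the primer sequence is prepended *and*
the first ten cycles get the low-diversity quality signature (mean raised
by ~3, sd ~0.5); the training corpus varies the baseline profile
(mean 30–38, sd 2–4) so the classifier must use the shape of the early
cycles, not an absolute quality level. Everything is deterministic per
seed, down to byte-identical FASTQ output.

What it does not emulate: indels and homopolymer noise, chimeras,
platform-specific error profiles, length jitter (optional window
simulation exists but the default fragment is fixed), or off-target
ITS/nifH contamination. Consequently, passing the simulation-based tests
demonstrates that the *machinery* — trimming, merging, alignment
coordinates, region attribution, coverage arithmetic, classifier wiring —
is correct under realistic substitution noise; it does not certify
accuracy on real archived data, whose error structure is richer. The
classifier stand-in result (held-out precision/recall ≥ 0.95 per class on
the simulated corpus) plays the same role: it verifies the feature/model
pipeline on a corpus constructed to be separable, not field performance.

## Numerical and interface choices

* Coordinates 0-based inclusive everywhere; the report prints floats with
  fixed 4-decimal formatting, booleans as TRUE/FALSE, missing values as NA.
* The report schema is 25 frozen snake_case columns (sample id; primer
  call and score; observed min start / max end; mean, median start/end;
  median-derived region calls; coverage-based calls with their coverages;
  warnings; Cov_V1–Cov_V9), golden-file tested.
* Phred+33 is assumed; apparent Phred+64 input is rejected with an explicit
  error rather than mis-decoded. Mates are matched by record order.
* Deterministic tie-breaks throughout: forward orientation on score ties,
  first-best column at the alignment end, forward base on consensus
  quality ties, first occurrence kept when accession lists are
  de-duplicated.
* Test problem sizes: the DP oracle runs on 200 random pairs up to length
  50; coverage is brute-forced on 50 random alignment sets; region
  recovery uses 20 replicates × 1,000 reads for each of the six catalog
  windows; the classifier corpus is 200 samples per class with 300 reads
  each. These sizes give exact or near-exact expectations while keeping
  the default suite fast.

## Known limitations

Bacterial 16S only, single reference, single-end FASTA amplicons get no
primer score (no qualities). Unmerged pairs are dropped rather than
aligned as fragments. The identity/score thresholds defining "alignment
error" are explicit choices, not archive-calibrated values. Remote
retrieval of run accessions is delegated to a pluggable fetch adapter
(`--fetch-cmd`); absent an adapter, accession input degrades to
`MISSING_FASTQ` rows by design.
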