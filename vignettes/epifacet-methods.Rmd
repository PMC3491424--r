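---
title: "Methods: keyword encoding, query semantics and null models in epifacet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keyword encoding, query semantics and null models in epifacet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifacet)
```

`epifacet` turns genomic region sets into searchable keyword documents and
answers faceted-search queries over them with exact counts.  This vignette
is the package's account of the underlying procedures, the parameters that
matter, the numerical choices, and what the synthetic test data do and do
not establish.

## Coordinates and the overlap concept

All coordinates are 0-based, half-open `[start, end)`, the BED convention,
because BED files are both the input and the export format.  Two intervals
overlap iff they share at least one base pair, so adjacent half-open
intervals (`[100,200)` and `[200,300)`) do *not* overlap, while `[100,200)`
and `[199,300)` share exactly one bp and do.  All overlap computations are
strand-blind; the strand column is carried through I/O untouched.  Distances
are gaps in bp between half-open intervals: adjacency is gap 0, and an
overlap also has gap 0, which is what "within 20 kb of the nearest gene"
filters operate on.

Interval arithmetic (per-region covered bp, nearest distance, union
coverage) is delegated to GenomicRanges/IRanges, converting at the boundary
(`IRanges(start + 1, end)`).  The test suite checks every one of these
operations against independent per-bp mask and all-pairs oracles, so the
conversion itself is under test.

## The keyword encoding

Each region document contains:

* `region:chrom:<chrom>`, `region:length:<code>`, and `region:score:<code>`
  when a BED score is present;
* one `overlap:<path>` word per overlapping track, with one extra
  `overlap:<path>:<category>` word per overlapping category of a
  chromatin-state track;
* one `overlapratio:<path>:<code>` word per annotated track (the fraction of
  the *region's own length* covered by the track union — the denominator
  choice that makes "regions mostly covered by X" filters work);
* `dnameth:<tissue>:ratio:<code>` and `dnameth:<tissue>:cov:<code>` when at
  least one measured CpG falls in the region — a region without measured
  CpGs carries no methylation words and is therefore excluded by any
  methylation filter;
* `dnaseq:freq:CG:<code>` and `dnaseq:freq:GC:<code>` when sequence
  composition is annotated;
* one `gene:<id>` word per gene within the proximity threshold, plus
  `distance:genes:<code>` for the nearest-gene gap.

### Numeric codecs

A codec is `(scale, width, clamp range)`: `code = floor(scale * v)` after
clamping, zero-padded to `width` digits.  Encoding is monotone
non-decreasing, so lexicographic (byte-order) comparison of words equals
numeric comparison at bin resolution, and a text range query is a numeric
range filter.  Defaults:

| attribute | scale | width | clamp | unit of the code |
|---|---|---|---|---|
| `dnaseq:freq:CG`, `dnaseq:freq:GC` | 1000 | 3 | [0, 0.999] | per-mille frequency |
| `dnameth:<t>:ratio` | 100 | 2 | [0, 0.99] | percent |
| `overlapratio:<path>` | 100 | 2 | [0, 0.99] | percent |
| `dnameth:<t>:cov` | 1 | 4 | [0, 9999] | CpG count |
| `region:length` | 1 | 8 | [0, 1e8) | bp |
| `region:score` | 1 | 6 | [0, 1e6) | score, floored |
| `distance:genes` | 1/1000 | 4 | [0, 1e7) bp | kb, floored |

The percent codecs clamp at 0.99 so a ratio of exactly 1 lands in the top
bin `99`; that is why "mostly methylated" can be written
`dnameth:ES:ratio:66--dnameth:ES:ratio:99` without a special case for fully
methylated regions.  The CpG-frequency denominator is the number of
dinucleotide positions (`length - 1`), a declared choice — the per-bp
alternative would be a one-line codec change.  The methylation mean is the
*unweighted* mean over measured positions; read coverage enters only through
the position-count filter, not as a weight.  Codecs live in a registry (a
flat TSV file via `read_codec_registry()`), so a new numeric attribute needs
a registry row, not code.

Two numerical guards matter.  First, bin codes are computed as
`floor(scale * v + 1e-9)`: products like `0.29 * 100` fall a few ulp below
the intended integer and the guard keeps exact bin boundaries in their bin,
while being six orders of magnitude smaller than any bin width in use.
Second, all dictionary order is byte order (`sort(method = "radix")` and a
rank-in-sorted-union comparison), never locale collation, so range and
prefix semantics cannot drift with the session locale.

## Query semantics

`parse_query()` implements: whitespace = And; `|` = Or, binding tighter than
And (this keeps the grammar parenthesis-free; the construction
`a b|c` means `a AND (b OR c)`); `low--high` = Range, inclusive on both
endpoints at word granularity (so `...:010--...:050` means "at least 1% and
not more than 5%" under floor binning); trailing `*` = Prefix; `@gene(...)`
= a join against the gene documents, with `~text` matching any gene carrying
an annotation term that contains `text` as a substring (term keywords are
lower-cased with non-alphanumerics mapped to `_`, so `~regulation` matches
`geneannot:go:regulation_of_transcription` and
`geneannot:go:negative_regulation_of_apoptosis` alike).  `@gene` cannot
nest.  A word absent from the dictionary is an empty result, not an error; a
malformed token (empty component, unbalanced parenthesis, range endpoints on
different attribute paths) is a parse error naming the token.

The index is an in-process sorted dictionary with sorted, duplicate-free
posting lists per namespace (region documents, gene documents).  It is a
pure function of the document multiset — insertion order cannot change the
serialized form — and serializes to its canonical document dump, from which
it rebuilds exactly.  Evaluation is plain set algebra, so `And` refinement
is monotone: a filter chain's cardinality ledger never increases, which is
asserted, not assumed.

Prefix completion returns one entry per dictionary word extending the
prefix with the count of matching (base) regions; with `rollup_level = k`
entries are grouped by the next `k` path components and each group counts
distinct regions (union semantics).  Both views are provided because
per-word and per-subtree counts answer different questions ("how many
regions per tissue" vs "how many regions for this mark at all").

## Analytics

* **Overlap summary / bubble data** — per track, `100 * |Term(overlap:p) ∩
  base| / |base|`; bubble data adds the track's genome coverage (union bp /
  assembly length) as the expected-by-chance x axis and optionally the
  control percentage.  When base and control sets differ in size, expected
  counts are scaled by `|base| / |control|`.
* **Histogram / pie partition** — histograms are prefix completions over a
  numeric path, so their counts are exactly the query engine's; pie
  partitions sum histogram bins between user edges and hand back one range
  query per segment as the drill-down.
* **Neighborhood profile** — regions are anchored at their midpoint;
  `2 * bins_per_side + 1` bins of width `flank_bp / bins_per_side` (defaults
  10 kb flank, 20 bins per side) are centred on the anchor, the middle bin
  straddling it.  A bin's value is the fraction of regions whose bin
  interval shares ≥ 1 bp with the track — binary overlap, not
  signal-weighted averaging, matching the package's overlap concept (no
  signal values are in scope).  Bins are clipped at chromosome edges and a
  region whose bin falls entirely off-chromosome leaves that bin's
  denominator.
* **Term enrichment** — per gene-annotation term: observed = base regions
  linked to ≥ 1 gene carrying the term (a genes-counting mode is available,
  since "enriched terms among nearby genes" is ambiguous between the two
  readings; regions is the default because the unit of analysis is the
  region set); expected = the same count over the control, scaled; ratio =
  `(observed + 1) / (expected + 1)`.  The pseudocount of one region avoids
  division by zero and makes `base == control` return exactly 1 for every
  term.  Terms carried by more than 5000 genes (too general) or fewer than
  50 (too specific) are suppressed by default.  No significance testing is
  attached — ratios are exploratory, like the word-cloud scaling they feed.

## The shuffle null

`shuffle_regions()` draws, for every region independently, a uniform
position among all (chromosome, start) pairs where the region fits — the
chromosome is chosen proportionally to its number of valid starts, i.e. the
null is genome-wide rather than per-chromosome, and shuffled regions may
overlap one another.  These are the two points where a "reshuffle the
positions" null needs pinning down; genome-wide-with-collisions is the
simplest exchangeable null that preserves the region count and the length
multiset exactly, and both choices are isolated behind this one function.
`expected_shuffle_overlap()` computes the exact analytic overlap probability
under this null (per region length: the union of track intervals expanded by
`length - 1` on the left, clipped to valid starts, over the number of valid
starts), which the Monte-Carlo tests compare against at 3 binomial standard
errors.

## The synthetic data generator

`generate_fixture()` emulates one study: a small multi-chromosome assembly
(default 4 × 2.5 Mb), a scored region set with log-uniform lengths (default
2000 regions, 200–3000 bp, integer scores 0–1000), interval tracks with an
exact genome-coverage target and a *planted enrichment factor*, genes placed
on region intervals with GO-style term vocabularies (half the genes carry a
term containing "regulation"), and a per-CpG methylation track with
stratified region means (low/intermediate/high) plus background CpGs outside
all regions.  Everything is deterministic given the seed, and the generator
emits a truth ledger computed by direct interval arithmetic on its own
layout — independent of the annotation/index pipeline — including the
survivor counts of a seven-step filter chain (length ≥ 1 kb, score ≥ 300,
mark overlap, `@gene(~regulation)`, second-track overlap, CpG coverage ≥ 5,
methylation 20–50%).

Planting an enrichment factor f needs care: the natural null for "f-fold
enriched" is the shuffle-null overlap probability of the final track layout,
and the planted in-region intervals themselves contribute to that null.  The
generator therefore solves for the hit count by fixed-point iteration —
lay out the track, compute the analytic null exactly, set
`hits = round(n * f * null)`, repeat until stable — and records both the hit
fraction and the null in the ledger, so a measured
(overlap %) / (shuffled-control %) ratio recovers f up to the control's
binomial noise.

What the generator does *not* emulate: real length and score distributions,
overlapping or nested regions, chromosome-specific composition, correlated
tracks, coverage-dependent methylation noise, and realistic GO term
hierarchies.  Passing tests therefore establish that the engine computes the
declared quantities exactly on data whose ground truth is known — not that
any biological association would be found in real data.

## Problem sizes and runtime choices

The test suite runs the query-engine oracle comparison at 1000 region and
200 gene documents with 200 random queries, codec checks at 10,000 values,
shuffle-null calibration at 2000 regions, enrichment recovery at 8000 short
regions (chosen so the planted factor 4 is satisfiable: with long regions
each planted hit inflates the null enough that high factors become
infeasible, which the generator detects and rejects), and the filter-chain
cascade at the default 2000 regions.  These sizes put every planted quantity
several standard errors inside its tolerance while keeping the whole suite
in the low minutes on one CPU.

## Known limitations

* Query evaluation materializes full posting lists; there is no compressed
  index, ranking, or typo tolerance, and very large dictionaries will pay
  linear prefix-scan costs.
* Ranges are closed word intervals: any word lexicographically between the
  endpoints matches, which is only meaningful for same-path numeric words —
  the parser enforces the shared path for that reason.
* The shuffle null does not condition on chromosome, GC content or
  annotation density; for biased genomes a stratified null would be needed.
* Enrichment ratios carry no p-values; exporting region/gene lists for
  dedicated statistical tools is the intended route.
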