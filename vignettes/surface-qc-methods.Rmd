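---
title: "Spatial and cycle-resolved QC: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial and cycle-resolved QC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtileqc)
```

## The model behind every metric

Deep-sequencing platforms image a two-dimensional surface in units —
tiles on an Illumina flowcell, panels on a SOLiD slide — and every read
identifier encodes the tile and the within-tile (x, y) position of the
cluster or bead it came from. The package's entire statistical machinery
rests on one null model: *library fragments attach to the surface at
random*, independently of their sequence content. Under this null, any
statistic computed over a region holding dozens to hundreds of reads —
the fraction of A bases or of color code 0, read density, mean quality,
the genomic hit rate — is flat across the surface up to sampling noise.
Composition itself is sample-specific and arbitrary; its *spatial
homogeneity* is not. A region enriched for A-rich reads, a low-quality
band below the sample inlet, a donut repeated at the same (x, y) of every
tile: each is evidence that the assay, not the biology, shaped the data.

The same logic powers the subset-QC feature. Reads supporting a specific
biological conclusion (a splice variant, a structural-change candidate)
are, under the null, a random subset of the sample, so their per-tile
distribution should be proportional to the whole sample's. Concentration
of "interesting" reads in a problematic region is grounds for suspicion,
and the package shows the subset map side by side with the whole-sample
map so the comparison is visual first, formal second.

## Coordinates, layouts and parsing

A `flowcell_layout` records the tile grid (rows × columns), the per-tile
coordinate extents, and positions unused by assay design (e.g. the four
corners of a slide). Layout files are a versioned plain-text schema
(`key: value` header plus one `row col tile_id [unused]` line per tile);
the format ships with two miniature examples under `inst/extdata/`.
Unused positions propagate as missing data through every sample-level
matrix and are excluded from heat-map auto-ranging, which is defined as
exactly the (min, max) of non-missing values.

Read identifiers are parsed in three dialects (pre-CASAVA colon format,
CASAVA 1.8+, SOLiD underscore format); the dialect is detected from the
first records and fixed per file, since real files never mix dialects.
Unparseable identifiers are *counted* per file as coordinate-less reads,
never silently dropped; a file is rejected only when more than half of
its first 1000 identifiers fail, which indicates a wrong format rather
than sporadic corruption. Platform coordinates are shifted to 0-based by
subtracting the per-file minimum, and tile extents are treated as
half-open upper bounds — this makes grid binning exact and is the least
surprising convention when extents come from a layout file rather than
from the data. Quality encodings are autodetected by a value-range scan
(any character below `;` forces Phred+33; above `J` forces Phred+64);
an ambiguous range defaults to +33 with a warning, the modern standard.
Colorspace reads keep their primer base as metadata so that quality
values align one-to-one with color calls, and `.`/`N` are no-calls:
counted in read totals, excluded from every composition denominator
("fraction of *called* symbols" throughout).

## Tunable parameters

* **Grid resolution** (default 20 × 20 cells per tile). The cell is the
  "fixed-size area" over which local composition and density are
  measured. 20 × 20 keeps cells large enough to hold dozens of reads at
  typical per-tile depths (thousands of reads) while resolving donuts and
  stripes; it is configurable everywhere (`grid_resolution`), and tests
  of sparse fixtures use 10 × 10 so that chi-square expectations stay
  honest.
* **Mismatch buckets** {0, 1, 2, ≥3}: the conventional bucketing for
  short-read alignment quality; reads with multiple hits contribute their
  best (fewest-mismatch) hit. Records lacking an NM tag go to an
  `unknown` bucket, counted but excluded from bucketed tallies.
* **Uniqueness** is derived tag-agnostically: an end is unique iff its
  normalized read id + mate maps exactly once in the file. This works for
  any aligner, old or new, at the cost of one extra pass over the ids.
* **Pair range** (`pair_config`, e.g. 500–5000 bp): the expected library
  separation. The range check is a *closed* interval on |distance| —
  separations of exactly 500 or 5000 are good — because the abnormal
  classes are defined as strictly "within" or strictly "over" the range.
  Distances keep their sign (`start1 − start2`) in the histograms, split
  by first-end strand, so strand bias is visible; only the magnitude is
  range-checked.
* **Orientation**: the expected configuration is convergent (the two
  ends on opposite strands); same-strand pairs are wrong-orientation
  chimeras. Real mate-pair protocols differ, so this sits behind the
  classification function rather than being hard-wired into parsing.
* **Quality summary**: per-tile and per-cell quality is the mean of
  per-base Phred scores (bases weighted equally, not reads). Weighting
  reads equally would let short or low-yield reads dominate sparse
  cells.

## The unevenness score

Tiles are ranked by `U = χ²/(k − 1)`, the Pearson chi-square of the k
within-tile cell counts against uniformity, divided by its degrees of
freedom. The normalization makes `U` comparable across tiles with equal
grids (`E[U] ≈ 1` under the null) and `U = 0` exactly iff all cells are
equal. Ties rank lexicographically by tile id; tiles with no data are
flagged and listed last. The 99th-percentile chi-square/df quantile is a
convenient alarm threshold: on flat synthetic data about 1% of tiles
exceed it (the acceptance suite requires ≤ 3% over 200 tiles).

The subset test uses the same statistic with expectations proportional
to whole-sample tile counts, pooling the smallest expectations until all
are ≥ 5. It is deliberately labelled *supplementary*: the primary
instrument is the side-by-side visual comparison, because a handful of
reads can never yield a decisive p-value yet can visibly pile onto a bad
region.

## Pooling, conservation, and precedence rules

All aggregation is count-weighted: counts are pooled first and divided
last, at every scope (cell → tile → row/column → sample), so results are
invariant to how tiles are grouped and robust to unequal tile depths.
This gives exact conservation laws — cell counts sum to tile counts,
per-cycle called + no-call counts equal read counts, stacked grids equal
cell-wise sums — which the test suite asserts exactly, not approximately.

Pair classification follows a fixed precedence: unpaired (exactly one
usable end) → different chromosome → wrong orientation → range check →
good. An end is usable when mapped and, by default, uniquely mapped —
chimera rates are meaningful only on unique hits, and non-unique ends are
treated like unmapped ones. Pairs with no usable end are excluded and
counted. The precedence order is a design choice (the categories must be
mutually exclusive and exhaustive, but several orders would achieve
that); it is validated against an independently written decision table
over all enumerable end configurations.

Coverage histograms count each read once at its alignment start rather
than building a per-base pileup: the plot's purpose is spotting uneven
target coverage and large-scale sample/reference differences, for which
start-binning is sufficient and much cheaper. Per-cycle mismatch masks
are reconstructed from MD tags of indel-free (single-M CIGAR)
alignments, flipped into read-cycle order for minus-strand hits; records
with indels are counted and excluded from the per-cycle rates (the
simulator emits none, and on real data they are a small minority for
the short-read platforms this targets).

## What the synthetic generator emulates — and what it does not

`simulate_flowcell()` produces reads whose identifiers encode the true
(tile, x, y), with stylized parametric pathologies:

* a linear left-to-right composition gradient across the chip
  (default study amplitude 0.05, emulating the 1–2% per-lane gradients
  seen in practice at an amplitude that desk-scale read counts can
  resolve);
* a periodic per-cycle excess of one symbol (period 5, amplitude 0.05 —
  the primer-reset periodicity of ligation chemistry);
* per-tile quality shifts and per-tile mappability (low-quality bands);
* cell-weight density masks, global (optics artifacts repeated on every
  tile) or per tile (a defect confined to one tile);
* per-cycle substitution rates and multi-hit fractions for alignments,
  with NM/MD tags constructed to match the injected mask exactly;
* exact pair-category mixtures with truncated-normal insert sizes
  (default mean 2000 bp, sd 300 bp inside a 500–5000 bp range).

One integer seed drives everything, and identical seeds give
byte-identical files. What the generator does *not* emulate: realistic
base-caller error models, optical duplicates, quality-score correlation
structure, indels, or adapter contamination. Passing the recovery suite
therefore shows that the metrics measure what they claim on data obeying
the stated null plus a known violation — it does not certify behaviour
on every real-world pathology. That is the right trade: the metrics are
counting statistics whose correctness is a bookkeeping property, and
bookkeeping is what synthetic truth can verify exactly.

Default validation sizes (chosen to make the stated tolerances
comfortably resolvable, and stated here as the package's study
conditions): 10^5 reads for gradient, periodic-bias and mismatch-rate
recovery; a 200-tile surface with 100 reads/tile for the stacked-donut
detection and 2000 reads/tile for null calibration; 500 replicates for
p-value uniformity; 1100 pairs for exact bookkeeping.

## Numerical and degenerate-input choices

* Composition fractions are `NA` (missing), never 0/0, for cells or
  scopes with no called symbols; missing cells render in a reserved
  color and never enter auto-ranged scales.
* `unevenness_score` is undefined (NA, with a warning) for empty or
  single-cell inputs rather than silently 0.
* The subset test refuses (< 2 cells after pooling) rather than
  returning an untrustworthy p-value.
* Coordinate collisions in the generator are redrawn so read ids are
  unique — duplicate ids would silently merge records downstream.
* Read files are validated structurally before parsing (line count
  multiple of 4; csfasta/qual headers pair 1:1 in order, first
  divergence named).

## The report and CLI

The HTML report is three-layered — samples, measure categories per
sample, then the plots — and entirely static. Every image has a sibling
TSV holding exactly the numbers it was drawn from: plots are views, never
the source of truth, and re-rendering unchanged results is
byte-identical. Subset maps render side by side with whole-sample maps
at identical scales and layout. The CLI (`inst/cli/seqtileqc.R`) exposes
`run`, `simulate`, `report` and `serve` subcommands; `serve` is a
minimal static-file HTTP server (default port 8080) provided for
convenience, the report needing no server to view.

## Known limitations

* Colorspace support covers composition/quality/spatial metrics;
  alignment simulation and alignment-derived metrics operate in base
  space (colorspace alignment is aligner-specific and upstream of this
  tool's contract, which consumes SAM).
* BAM/CRAM input is out of scope; alignments are consumed as SAM from
  any aligner that writes NM tags.
* The tool reports and ranks; it does not classify root causes
  (fluidics vs optics) or decide which biological candidates to discard.
* Per-cycle mismatch rates require MD tags and indel-free alignments;
  without MD the per-tile tallies still work from NM alone.
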