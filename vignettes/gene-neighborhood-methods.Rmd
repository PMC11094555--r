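---
title: "Comparing microbial gene neighborhoods: models, parameters and design notes"
author: "GeneNeighborhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microbial gene neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneNeighborhoods)
```

## The problem

A gene's genomic context in bacteria and archaea — the identity, order and
orientation of its neighbors — is evidence about its function. Conserved
blocks suggest operons and co-functioning pathways; lineage-specific
insertions flag mobile elements; inversions and rearrangements record
evolutionary history. This package turns annotated genomes into comparable,
clusterable, drawable *neighborhood* objects. This vignette documents the
models and the decisions behind them; the README shows the surface API.

## Neighborhood extraction

`extractNeighborhood()` takes the window
`[max(1, anchor_start − W), min(contig_length, anchor_end + W)]`
and keeps exactly the genes whose intervals lie fully inside it. Three
choices deserve justification:

* **Window anchored at the gene's boundaries, not its midpoint.** "±W"
  around a gene is ambiguous; measuring from the anchor's start and end
  guarantees the window always contains the whole anchor regardless of its
  length, so an anchor can never exclude itself. W (`windowBp`) defaults to
  10 000 bp per side — roughly ten average bacterial CDSs, enough to span
  typical operons.
* **Edge exclusion.** A gene that crosses a window boundary is dropped
  rather than truncated: a clipped gene would misrepresent both its length
  and its annotation, and partial genes cannot participate meaningfully in
  the content alignment. The exclusion applies to neighbors only; the
  anchor is always retained.
* **Linear contigs.** Windows truncate at position 1 and at the contig
  length. Circular replicons are not wrapped: near-origin anchors on
  circular genomes therefore get one-sided neighborhoods. Wrapping would
  require topology metadata that neither GFF3 nor most GenBank records
  supply reliably.

Orientation is display state, not data: `flipNeighborhood()` reflects
coordinates within the window (`new_start = ws + we − end`), toggles
strands, and is an involution, so source coordinates are always
recoverable. `normalizeOrientation()` flips exactly those neighborhoods
whose anchor is on the minus strand, which makes stacked tracks comparable
and is idempotent.

## The content alignment

Neighborhoods are compared through their **label vectors**: per-gene label
*sets* in one annotation namespace (a gene may carry several Pfam domains).
`localAlign()` runs a Smith–Waterman-style dynamic program over gene
positions with a cell floor of zero, implemented in C++ for the all-pairs
workloads clustering generates.

Decisions, each exposed as a parameter so other schemes are recoverable:

* **Match predicate = non-empty set intersection.** The least surprising
  generalization of label equality to set-valued annotations; one shared
  domain suffices.
* **Unannotated genes never match, including each other.** Runs of
  hypothetical proteins would otherwise make any two sparsely annotated
  neighborhoods look alike. They can still be crossed by gaps or absorbed
  as mismatches when context makes it worthwhile.
* **Scores +1 / −1 / −1** (match / mismatch / gap). With these defaults a
  conserved block of *k* annotated genes scores exactly *k*, which makes
  scores readable; the `alignParams()` invariants (`match > 0`,
  `gap ≤ 0`, `mismatch ≤ match`) keep any user scheme well-posed.
* **Reversed-orientation pass** (`tryReverse`, on by default): the second
  vector is also aligned reversed and the better orientation reported.
  This is what lets wholesale inversions — common at operon scale — align;
  strand itself is deliberately ignored by the match predicate, since gene
  *content*, not strand, defines neighborhood similarity.
* **Deterministic traceback**: best cell with the smallest `(i, j)` on
  ties, diagonal preferred over up over left. Aligned pairs are therefore
  reproducible, not just scores.

`alignScoreExhaustive()` is a deliberately independent reference: it
enumerates every chain of aligned position pairs (strictly increasing in
both coordinates, interior gap-penalized, free ends) and maximizes the
score directly. It is exponential and only usable for short vectors, which
is exactly its job — the test suite and the acceptance script hold the DP
to 100 % agreement with it on thousands of random short vectors.

## Similarity, distance, clustering

`contextSimilarity()` normalizes the cross-score by the *smaller*
self-score (self-scores computed without the reversed pass):
`sim = SW(u,v) / min(SW(u,u), SW(v,v))`, clipped to `[0, 1]`. Dividing by
the smaller self-score makes the measure scale-free in neighborhood length:
a short neighborhood fully contained in a longer one scores 1, which is the
behavior wanted when windows truncate at contig ends. Two entirely
unannotated neighborhoods get similarity 0 with a warning rather than 0/0.

`clusterNeighborhoods()` feeds `d = 1 − sim` to `stats::hclust()` with
average linkage — a robust default when no linkage is dictated — and reads
the display order off the dendrogram with a deterministic rule: at every
merge the subtree containing the smaller original index goes left. Identical
neighborhoods are at distance 0, merge first, and are therefore always
adjacent. An optional `anchored` mode additionally requires the two anchors
to be an aligned pair (similarity 0 otherwise); it is off by default, since
anchor-centered sorting plus content alignment already keeps anchors in
register in practice.

## File formats

* **GFF3** is read through `rtracklayer::readGFF` (CDS features only;
  skipped feature counts are reported). Labels come from
  `Dbxref`/`Ontology_term` entries with `Pfam:`/`KEGG:`/`TIGR:` prefixes
  and from `kegg=`/`pfam=`/`tigrfam=` attributes. Contig lengths come from
  `##sequence-region`; a missing pragma degrades to the maximum feature end
  with a warning.
* **GenBank** flat files are parsed by a purpose-built feature-table reader
  (no installed package parses GenBank feature tables). Compound
  `join(...)` locations collapse to their outer span with a warning —
  fine for the microbial CDSs this package targets, lossy for
  spliced eukaryotic genes, which are out of scope.
* **Neighborhood CSV** is this package's canonical interchange format: the
  fixed columns `neighborhood_id, genome_id, taxonomy, contig_id, gene_id,
  start, end, strand, product, is_anchor`, one lowercased column per
  namespace (multi-label cells comma-joined), then optional `protein_seq`.
  Window bounds and the flip flag are display state and are *not*
  serialized; reading reconstructs the window as the gene span. Round-trip
  identity therefore covers every serialized field, and a written file
  re-read and re-written reproduces itself byte for byte.
* **Hit tables** are 12-column tabular alignment output, optionally
  extended with `qcovhsp`/`scovhsp` and a GTDB lineage string. Missing
  coverage columns default to 100 (non-restrictive) with a warning, because
  plain 12-column output is the de-facto standard and failing on it would
  help nobody. Coordinates are 1-based inclusive everywhere — the native
  convention of GFF3 and GenBank — so no conversion ever happens at the
  boundaries.

## Rendering

`renderSvg()` is a pure function from a `NeighborhoodSet` (plus options) to
an SVG string: no timestamps, no randomness, fixed number formatting, hence
byte-identical output — diffs of figures are meaningful. Geometry: 1 kb =
`pxPerKb` (default 40 px), arrow glyphs whose horizontal extent is exactly
`(end − start + 1)` scaled, tracks translated so anchor midpoints share one
x-coordinate when `centerOnAnchor` is on. The coloring rule highlights
labels occurring **more than twice** across the figure
(`highlightMinCount = 3`, counting once per gene per distinct label) with a
fixed 20-color qualitative palette assigned in descending-count order,
lexicographic on ties, recycled with a warning beyond 20. A hard cap of
500 tracks per figure keeps documents tractable for browsers and vector
editors; exceeding it is an error, not a silent truncation. Overlapping
genes draw in coordinate order with later genes on top — microbial CDS
overlaps are a few bp, so collision layout is not worth its complexity.

## Synthetic data: what it emulates, what it does not

`generateNeighborhoodSet()` plants the three structures the comparison
machinery must detect: a conserved core block (an operon proxy) present in
a stated fraction of neighborhoods, optional inversion of that block, and
optional insertions carrying labels unique to one neighborhood (a mobile
element proxy). Geometry is realistic for microbial genomes — gene lengths
300–1500 bp, intergenic gaps 50–200 bp, non-overlapping — and every
realization is a full `GenomeRecord`, so extraction, file writers and the
CLI are exercised on the same objects. All randomness flows from the single
spec seed via `withr::with_seed`; the global RNG stream is untouched and
equal specs give byte-identical files.

What the generator does **not** emulate: annotation noise (mislabeled or
partially annotated core genes), homologous-but-diverged labels, gene
fission/fusion, overlapping CDSs, and any realistic protein or nucleotide
sequence content. Passing the planted-structure tests therefore shows the
pipeline recovers clean signal reliably; it does not bound performance on
noisy real annotations, where similarity is graded rather than 0/1.

Problem sizes used by the test suite and `scripts/acceptance.R` — 10 000
oracle-vs-DP vector pairs, 1 000 random genomes for the window-rule audit,
200 clustering replicates of 8 neighborhoods, 10 000 synthetic hits — were
chosen so each check has comfortable statistical teeth while the whole
suite stays in the minutes range on one core.

## Known limitations

* Circular replicons are treated as linear (above).
* GenBank compound locations lose their intron/exon structure.
* Similarity is content-based only; intergenic distances and gene lengths
  do not enter the score.
* The label-set match predicate is exact string equality within a
  namespace; it does not know about Pfam clans or KO hierarchies.
* `readGff3`/`readGenBank` ingest protein-coding features only; tRNA/rRNA
  and repeat features are counted and skipped.
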