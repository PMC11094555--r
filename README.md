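# GeneNeighborhoods

Offline extraction, comparison and visualization of microbial gene
neighborhoods.

In bacteria and archaea, the genes surrounding a gene of interest — its
*gene neighborhood* — carry functional signal: operons, secretion systems,
biosynthetic clusters and toxin/antitoxin insertions all show up as
conserved (or conspicuously rearranged) local gene content. This package is
for microbial genomicists who have annotated genomes (GFF3 or GenBank) or
homology-search hit tables on disk and want to:

1. **extract** the neighborhood around anchor genes — every protein-coding
   gene fully contained in a ±W bp window (default W = 10 kb) around the
   anchor, with genes crossing a window edge excluded;
2. **compare and cluster** neighborhoods by the similarity of their gene
   content;
3. **render** the result as a deterministic multi-track SVG figure with
   frequency-based gene coloring.

## The method

Each neighborhood is projected onto an annotation namespace (KEGG, Pfam,
TIGRFAM or any custom vocabulary) as an ordered vector of per-gene label
sets `L_1, …, L_n`. Two neighborhoods are compared with a
Smith–Waterman-style local alignment over gene positions: positions *i*, *j*
match iff `L_i ∩ M_j ≠ ∅`, and the score matrix follows

    H(i,j) = max{ 0,
                  H(i-1,j-1) + s(i,j),   s(i,j) = +1 match / −1 mismatch
                  H(i-1,j)   − 1,        (gap)
                  H(i,j-1)   − 1 }

with the alignment also tried against the reversed second vector, so
inverted gene clusters still align. Pairwise similarity is the alignment
score normalized by the smaller self-alignment score,
`sim(u,v) = SW(u,v) / min(SW(u,u), SW(v,v)) ∈ [0,1]`, and neighborhoods are
ordered by average-linkage hierarchical clustering of `d = 1 − sim` with a
deterministic dendrogram leaf order. Homology hit lists (tabular
"outfmt 6") are filtered with the standard annotation-transfer thresholds —
E-value ≤ 1e-5, identity ≥ 30 %, query↔subject coverage ≥ 70 % — before
top-N or by-lineage selection.

All data containers are Bioconductor-style S4 classes (`GenomeRecord`,
`Neighborhood`, `NeighborhoodSet` on top of `GRanges`/`SimpleList`), and a
seeded synthetic-data module (`fixtureSpec()`, `generateNeighborhoodSet()`,
`generateHits()`) makes the entire workflow runnable offline.

## Worked example

```r
library(GeneNeighborhoods)

# a synthetic 6-genome dataset with a conserved 5-gene core operon,
# 40% of copies inverted, written to disk in GFF3/GenBank/CSV
s <- generateNeighborhoodSet(
  fixtureSpec(nNeighborhoods = 6, inversionProb = 0.4, seed = 7),
  dir = "demo")
s
#> NeighborhoodSet: 6 neighborhood(s), active namespace 'Pfam', rank 'species'
#>   nbh001, nbh002, nbh003, nbh004, nbh005, ...

s <- normalizeOrientation(s)          # all anchors onto the + strand
co <- clusterNeighborhoods(s)         # SW similarity + average linkage
leafOrder(co)
#> [1] 1 2 3 4 5 6
round(distanceMatrix(co)[1:3, 1:3], 2)
#>        nbh001 nbh002 nbh003
#> nbh001      0      0      0
#> nbh002      0      0      0
#> nbh003      0      0      0

svg <- renderSvg(applyOrdering(s, co))
writeLines(svg, "figure.svg")
```

All six neighborhoods share the full core block, so every pairwise distance
is 0 (inverted copies are recovered through the reversed-orientation
alignment) and the tracks stack into one cluster. Aligning two
neighborhoods directly:

```r
u <- labelVector(s[[1]], "Pfam")
v <- labelVector(s[[2]], "Pfam")
localAlign(u, v)
#> AlignmentResult: score 5, 5 aligned pair(s)
contextSimilarity(u, v)
#> [1] 1
```

The score 5 is the five matched core genes; similarity 1 means the shared
block covers the smaller neighborhood's entire annotated content.

The same pipeline runs from the shell (`inst/scripts/gnhood`):

```sh
gnhood extract demo/fixture.gff3 --anchor-label PF00100 --namespace Pfam -o nbh.csv
gnhood cluster nbh.csv --namespace Pfam -o ordered.csv     # + ordered.csv.sim.tsv
gnhood render ordered.csv --namespace Pfam -o figure.svg
gnhood filter-hits hits.tsv --top-n 50 -o filtered.tsv
```

Exit codes: 0 success, 2 input/validation error, 3 limit exceeded (e.g.
more than 500 tracks).

## SVG anatomy

Each neighborhood is one `<g class="track">`; each gene a
`<polygon class="gene">` arrow (point follows strand, 40 px/kb by default)
carrying `data-gene-id`, `data-neighborhood-id` and `data-labels`
attributes; swatches live in `<g class="legend">`. Labels occurring more
than twice across the figure are colored from a fixed 20-color palette
(descending count, lexicographic ties); everything else is gray
(`#c8c8c8`). Output is timestamp-free and byte-identical across runs, so
figures diff cleanly and edit well in Inkscape or Illustrator.

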