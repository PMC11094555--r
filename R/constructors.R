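#' Build a GRanges of genes from plain vectors
#'
#' Convenience constructor for the gene container used throughout the
#' package: a [GenomicRanges::GRanges] with `gene_id` and `product`
#' metadata columns plus one [IRanges::CharacterList] column per annotation
#' namespace.
#'
#' @param contigId contig name (recycled to the number of genes).
#' @param geneId character vector of unique gene identifiers.
#' @param start,end 1-based inclusive coordinates (`end >= start`).
#' @param strand character vector of `"+"`/`"-"`.
#' @param product free-text product descriptions (default empty strings).
#' @param labels named list mapping namespace name (e.g. `"Pfam"`) to a list
#'   of per-gene character vectors of labels. Missing genes get empty sets.
#' @param proteinSeq optional character vector of amino-acid sequences
#'   (`NA` where absent).
#' @param sort sort genes by (start, end)? Default `TRUE`.
#' @return a `GRanges` suitable for the `genes` slot of [GenomeRecord-class].
#' @examples
#' gr <- geneRanges("ctg1", c("g1", "g2"), c(100, 900), c(400, 1200),
#'                  c("+", "-"), labels = list(Pfam = list("PF00001", character(0))))
#' @export
geneRanges <- function(contigId, geneId, start, end, strand,
                       product = rep("", length(geneId)),
                       labels = list(), proteinSeq = NULL, sort = TRUE) {
  n <- length(geneId)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(contigId, length.out = max(n, 0L)),
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
    strand = strand
  )
  mc <- S4Vectors::DataFrame(gene_id = as.character(geneId),
                             product = as.character(product))
  for (ns in names(labels)) {
    val <- labels[[ns]]
    if (length(val) < n) val <- c(val, rep(list(character(0)), n - length(val)))
    val <- lapply(val, function(x) as.character(x[nzchar(x)]))
    mc[[ns]] <- IRanges::CharacterList(val)
  }
  if (!is.null(proteinSeq)) mc$protein_seq <- as.character(proteinSeq)
  S4Vectors::mcols(gr) <- mc
  if (sort && n > 1L)
    gr <- gr[order(GenomicRanges::start(gr), GenomicRanges::end(gr))]
  gr
}

#' Construct a GenomeRecord
#'
#' @param contigId contig name.
#' @param genes a `GRanges` built like [geneRanges()] output.
#' @param contigLength contig length in bp; when `NULL`, inferred from the
#'   largest gene end.
#' @param genomeId genome/assembly identifier (defaults to `contigId`).
#' @param taxonomy a `rank`/`name` data.frame (see [parseTaxonomy()]) or a
#'   GTDB-style prefixed string.
#' @return a [GenomeRecord-class] object.
#' @examples
#' gr <- geneRanges("ctg1", "g1", 100, 400, "+")
#' genomeRecord("ctg1", gr, contigLength = 5000)
#' @export
genomeRecord <- function(contigId, genes, contigLength = NULL,
                         genomeId = contigId, taxonomy = .emptyTaxonomy()) {
  if (is.character(taxonomy)) taxonomy <- parseTaxonomy(taxonomy)
  if (is.null(contigLength))
    contigLength <- if (length(genes)) max(GenomicRanges::end(genes)) else 1L
  new("GenomeRecord", genomeId = genomeId, contigId = contigId,
      contigLength = as.integer(contigLength), taxonomy = taxonomy,
      genes = genes)
}

#' Construct a Neighborhood directly
#'
#' Usually neighborhoods come from [extractNeighborhood()] or
#' [readNeighborhoodCsv()]; this low-level constructor is exposed for
#' programmatic assembly.
#'
#' @param neighborhoodId unique identifier.
#' @param anchorId `gene_id` of the anchor; must be among `genes`.
#' @param genes gene `GRanges` (display orientation).
#' @param windowStart,windowEnd window bounds (default: the gene span).
#' @param flipped display orientation flag.
#' @param genomeId,contigId,taxonomy source metadata.
#' @return a [Neighborhood-class] object.
#' @export
neighborhood <- function(neighborhoodId, anchorId, genes,
                         windowStart = NULL, windowEnd = NULL,
                         flipped = FALSE, genomeId = "", contigId = "",
                         taxonomy = .emptyTaxonomy()) {
  if (is.character(taxonomy)) taxonomy <- parseTaxonomy(taxonomy)
  if (is.null(windowStart))
    windowStart <- if (length(genes)) min(GenomicRanges::start(genes)) else 1L
  if (is.null(windowEnd))
    windowEnd <- if (length(genes)) max(GenomicRanges::end(genes)) else 1L
  new("Neighborhood", neighborhoodId = neighborhoodId, anchorId = anchorId,
      genes = genes, windowStart = as.integer(windowStart),
      windowEnd = as.integer(windowEnd), flipped = flipped,
      genomeId = genomeId, contigId = contigId, taxonomy = taxonomy)
}

#' Construct a NeighborhoodSet
#'
#' @param neighborhoods a list of [Neighborhood-class] objects (or several
#'   passed as `...`).
#' @param activeNamespace annotation namespace used for clustering and
#'   coloring (default `"KEGG"`, the platform default).
#' @param taxonomyRank rank shown on track labels (default `"species"`).
#' @return a [NeighborhoodSet-class].
#' @export
neighborhoodSet <- function(neighborhoods = list(), ...,
                            activeNamespace = "KEGG",
                            taxonomyRank = "species") {
  if (is(neighborhoods, "Neighborhood"))
    neighborhoods <- list(neighborhoods)
  neighborhoods <- c(neighborhoods, list(...))
  new("NeighborhoodSet", listData = unname(neighborhoods),
      activeNamespace = activeNamespace, taxonomyRank = taxonomyRank)
}
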