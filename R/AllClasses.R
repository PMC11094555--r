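#' @import methods
#' @importFrom S4Vectors SimpleList mcols mcols<- DataFrame isSorted
#' @importFrom GenomicRanges GRanges start end strand strand<- ranges
#' @importFrom IRanges IRanges CharacterList
#' @useDynLib GeneNeighborhoods, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom utils head
#' @importFrom stats setNames
NULL

.CANONICAL_RANKS <- c("domain", "phylum", "class", "order", "family",
                      "genus", "species")

## taxonomy is carried around as a data.frame with columns rank, name
.emptyTaxonomy <- function() {
  data.frame(rank = character(0), name = character(0),
             stringsAsFactors = FALSE)
}

.validTaxonomy <- function(tax) {
  if (!is.data.frame(tax) || !all(c("rank", "name") %in% names(tax)))
    return("taxonomy must be a data.frame with columns 'rank' and 'name'")
  if (nrow(tax) == 0L)
    return(NULL)
  if (!all(tax$rank %in% .CANONICAL_RANKS))
    return(paste0("unknown taxonomy rank(s): ",
                  paste(setdiff(tax$rank, .CANONICAL_RANKS), collapse = ", ")))
  if (anyDuplicated(tax$rank))
    return("taxonomy ranks must appear at most once")
  idx <- match(tax$rank, .CANONICAL_RANKS)
  if (is.unsorted(idx))
    return("taxonomy ranks must be in canonical order (domain..species)")
  NULL
}

## Gene-level validity shared by GenomeRecord and Neighborhood: genes live in
## a GRanges whose mcols carry gene_id, product and zero or more
## CharacterList annotation-namespace columns.
.validGeneRanges <- function(gr, requireSorted = TRUE) {
  msg <- character(0)
  mc <- S4Vectors::mcols(gr)
  if (!all(c("gene_id", "product") %in% names(mc)))
    return("gene ranges need mcols 'gene_id' and 'product'")
  if (length(gr)) {
    if (anyDuplicated(mc$gene_id))
      msg <- c(msg, "duplicate gene id")
    if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    if (any(GenomicRanges::start(gr) < 1L))
      msg <- c(msg, "gene start coordinates must be >= 1")
    if (requireSorted) {
      o <- order(GenomicRanges::start(gr), GenomicRanges::end(gr))
      if (!identical(o, seq_along(gr)))
        msg <- c(msg, "genes must be sorted by (start, end)")
    }
    for (ns in .namespaceColumns(gr)) {
      labs <- unlist(mc[[ns]], use.names = FALSE)
      if (any(!nzchar(labs)))
        msg <- c(msg, sprintf("namespace '%s' contains empty label strings", ns))
    }
  }
  if (length(msg)) msg else NULL
}

## annotation-namespace columns = every CharacterList mcol that is not a
## reserved bookkeeping column
.RESERVED_MCOLS <- c("gene_id", "product", "protein_seq")
.namespaceColumns <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  nms <- setdiff(names(mc), .RESERVED_MCOLS)
  nms[vapply(nms, function(x) is(mc[[x]], "CharacterList"), logical(1))]
}

#' GenomeRecord: one annotated contig or replicon
#'
#' Holds a single contig's protein-coding genes as a [GenomicRanges::GRanges]
#' (1-based inclusive coordinates, strand `+`/`-`), together with genome-level
#' metadata and GTDB-style taxonomy. Gene metadata columns are `gene_id`,
#' `product`, optionally `protein_seq`, plus one
#' [IRanges::CharacterList] column per annotation namespace (e.g. `KEGG`,
#' `Pfam`, `TIGRFAM`).
#'
#' @slot genomeId single string naming the source genome/assembly.
#' @slot contigId single string naming the contig.
#' @slot contigLength contig length in bp; at least the largest gene end.
#' @slot taxonomy data.frame with columns `rank`, `name`; ranks drawn from
#'   domain/phylum/class/order/family/genus/species in canonical order.
#' @slot genes `GRanges` of CDS features sorted by (start, end).
#'
#' @seealso [genomeRecord()], [extractNeighborhood()], [readGff3()],
#'   [readGenBank()]
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(
    genomeId = "character",
    contigId = "character",
    contigLength = "integer",
    taxonomy = "data.frame",
    genes = "GRanges"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character(0)
  if (length(object@contigId) != 1L || !nzchar(object@contigId))
    msg <- c(msg, "contigId must be a single non-empty string")
  if (length(object@contigLength) != 1L || is.na(object@contigLength) ||
      object@contigLength < 1L)
    msg <- c(msg, "contigLength must be a positive integer")
  tmsg <- .validTaxonomy(object@taxonomy)
  if (!is.null(tmsg)) msg <- c(msg, tmsg)
  gmsg <- .validGeneRanges(object@genes)
  if (!is.null(gmsg)) msg <- c(msg, gmsg)
  if (length(object@genes) &&
      max(GenomicRanges::end(object@genes)) > object@contigLength)
    msg <- c(msg, "gene end beyond contig length")
  if (length(msg)) msg else TRUE
})

#' Neighborhood: an anchor gene and its windowed genomic context
#'
#' The genes of one contig that fall entirely inside the extraction window
#' around an anchor gene, in display orientation. Coordinates are display
#' coordinates: after [flipNeighborhood()] they are the reflection of the
#' source coordinates within the window and `flipped` is `TRUE`.
#'
#' @slot neighborhoodId unique identifier within a [NeighborhoodSet].
#' @slot anchorId `gene_id` of the anchor gene (always present in `genes`).
#' @slot genes `GRanges` in display orientation, sorted by (start, end).
#' @slot windowStart,windowEnd window bounds on the source contig (bp).
#' @slot flipped `TRUE` when display orientation is reversed.
#' @slot genomeId,contigId provenance of the source contig.
#' @slot taxonomy source genome taxonomy (`rank`/`name` data.frame).
#'
#' @seealso [extractNeighborhood()], [flipNeighborhood()], [labelVector()]
#' @exportClass Neighborhood
setClass("Neighborhood",
  representation(
    neighborhoodId = "character",
    anchorId = "character",
    genes = "GRanges",
    windowStart = "integer",
    windowEnd = "integer",
    flipped = "logical",
    genomeId = "character",
    contigId = "character",
    taxonomy = "data.frame"
  )
)

setValidity("Neighborhood", function(object) {
  msg <- character(0)
  if (length(object@neighborhoodId) != 1L || !nzchar(object@neighborhoodId))
    msg <- c(msg, "neighborhoodId must be a single non-empty string")
  gmsg <- .validGeneRanges(object@genes)
  if (!is.null(gmsg)) msg <- c(msg, gmsg)
  if (!object@anchorId %in% S4Vectors::mcols(object@genes)$gene_id)
    msg <- c(msg, "anchor gene must be among the neighborhood genes")
  if (object@windowStart > object@windowEnd)
    msg <- c(msg, "windowStart must be <= windowEnd")
  if (length(object@genes)) {
    if (any(GenomicRanges::start(object@genes) < object@windowStart) ||
        any(GenomicRanges::end(object@genes) > object@windowEnd))
      msg <- c(msg, "all genes must lie within [windowStart, windowEnd]")
  }
  tmsg <- .validTaxonomy(object@taxonomy)
  if (!is.null(tmsg)) msg <- c(msg, tmsg)
  if (length(msg)) msg else TRUE
})

#' NeighborhoodSet: an ordered collection of neighborhoods
#'
#' A [S4Vectors::SimpleList] of [Neighborhood] objects sharing an active
#' annotation namespace (used for coloring and clustering) and a taxonomy
#' rank used for track labels. The list order is the display order.
#'
#' @slot activeNamespace namespace used by [clusterNeighborhoods()],
#'   [assignColors()] and [renderSvg()]; default `"KEGG"`.
#' @slot taxonomyRank rank displayed on track labels; default `"species"`.
#'
#' @seealso [neighborhoodSet()], [normalizeOrientation()],
#'   [clusterNeighborhoods()], [renderSvg()]
#' @exportClass NeighborhoodSet
setClass("NeighborhoodSet",
  contains = "SimpleList",
  representation(
    activeNamespace = "character",
    taxonomyRank = "character"
  ),
  prototype(
    elementType = "Neighborhood",
    activeNamespace = "KEGG",
    taxonomyRank = "species"
  )
)

setValidity("NeighborhoodSet", function(object) {
  msg <- character(0)
  if (length(object@activeNamespace) != 1L || !nzchar(object@activeNamespace))
    msg <- c(msg, "activeNamespace must be a single non-empty string")
  if (!object@taxonomyRank %in% .CANONICAL_RANKS)
    msg <- c(msg, "taxonomyRank must be a canonical rank name")
  if (length(object)) {
    ids <- vapply(object, function(n) n@neighborhoodId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "neighborhood ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' LabelVector: a neighborhood projected onto one annotation namespace
#'
#' The ordered list of per-gene label sets (character vectors, possibly
#' empty) that [localAlign()] operates on, plus the anchor position.
#'
#' @slot entries list of character vectors, one per gene in display order.
#' @slot anchorIndex 1-based position of the anchor gene.
#' @slot sourceId `neighborhoodId` the vector was derived from.
#'
#' @seealso [labelVector()], [localAlign()], [contextSimilarity()]
#' @exportClass LabelVector
setClass("LabelVector",
  representation(
    entries = "list",
    anchorIndex = "integer",
    sourceId = "character"
  )
)

setValidity("LabelVector", function(object) {
  msg <- character(0)
  if (length(object@entries) < 1L)
    msg <- c(msg, "empty neighborhood")
  if (object@anchorIndex < 1L || object@anchorIndex > length(object@entries))
    msg <- c(msg, "anchorIndex out of range")
  if (!all(vapply(object@entries, is.character, logical(1))))
    msg <- c(msg, "entries must be character vectors")
  if (length(msg)) msg else TRUE
})

#' AlignmentResult: outcome of a local gene-order alignment
#'
#' @slot score best local alignment score (>= 0; the local-alignment floor).
#' @slot pairs integer matrix with columns `u`, `v`: aligned positions
#'   (matched or mismatched), strictly increasing in both coordinates. When
#'   `reversed` is `TRUE` the `v` column indexes the reversed vector.
#' @slot reversed `TRUE` when the better score came from aligning against
#'   the reversed second vector.
#'
#' @seealso [localAlign()]
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(
    score = "numeric",
    pairs = "matrix",
    reversed = "logical"
  )
)

#' ClusterOrdering: a clustered display order for a NeighborhoodSet
#'
#' @slot order permutation of `seq_len(n)`: dendrogram leaf order.
#' @slot distanceMatrix symmetric n x n matrix of `1 - similarity` values
#'   in `[0, 1]` with zero diagonal.
#' @slot linkageMethod agglomeration method used (default `"average"`).
#'
#' @seealso [clusterNeighborhoods()]
#' @exportClass ClusterOrdering
setClass("ClusterOrdering",
  representation(
    order = "integer",
    distanceMatrix = "matrix",
    linkageMethod = "character"
  )
)

setValidity("ClusterOrdering", function(object) {
  msg <- character(0)
  n <- nrow(object@distanceMatrix)
  if (!identical(sort(object@order), seq_len(n)))
    msg <- c(msg, "order must be a permutation of 1..n")
  if (n != ncol(object@distanceMatrix))
    msg <- c(msg, "distance matrix must be square")
  if (n) {
    d <- object@distanceMatrix
    if (max(abs(d - t(d))) > 1e-8)
      msg <- c(msg, "distance matrix must be symmetric")
    if (any(d < -1e-8) || any(d > 1 + 1e-8))
      msg <- c(msg, "distances must lie in [0, 1]")
    if (any(abs(diag(d)) > 1e-8))
      msg <- c(msg, "distance matrix diagonal must be zero")
  }
  if (length(msg)) msg else TRUE
})
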