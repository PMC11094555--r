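#' @name accessors
#' @title Accessors for GeneNeighborhoods classes
#'
#' @description Slot accessors: `genes()` returns the gene `GRanges` of a
#' [GenomeRecord-class] or [Neighborhood-class]; `anchorId()`,
#' `neighborhoodId()`, `windowBounds()`, `isFlipped()` expose neighborhood
#' state; `taxonomyOf()` returns the `rank`/`name` taxonomy data.frame;
#' `activeNamespace()`/`taxonomyRank()` (with replacement forms) expose
#' display state of a [NeighborhoodSet-class]; `namespaces()` lists the
#' annotation namespaces present; `geneLabels()` returns one gene's label
#' set in a namespace; `anchorGene()` returns the anchor as a length-1
#' `GRanges`.
#'
#' @param x an object of the documented class.
#' @param value replacement value.
#' @param namespace annotation namespace name.
#' @param geneId gene identifier.
#' @return see Description.
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GenomeRecord", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("genes", "Neighborhood", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("anchorId", function(x) standardGeneric("anchorId"))
#' @rdname accessors
#' @export
setMethod("anchorId", "Neighborhood", function(x) x@anchorId)

#' @rdname accessors
#' @export
setGeneric("neighborhoodId", function(x) standardGeneric("neighborhoodId"))
#' @rdname accessors
#' @export
setMethod("neighborhoodId", "Neighborhood", function(x) x@neighborhoodId)

#' @rdname accessors
#' @export
setGeneric("windowBounds", function(x) standardGeneric("windowBounds"))
#' @rdname accessors
#' @export
setMethod("windowBounds", "Neighborhood",
          function(x) c(start = x@windowStart, end = x@windowEnd))

#' @rdname accessors
#' @export
setGeneric("isFlipped", function(x) standardGeneric("isFlipped"))
#' @rdname accessors
#' @export
setMethod("isFlipped", "Neighborhood", function(x) x@flipped)

#' @rdname accessors
#' @export
setGeneric("taxonomyOf", function(x) standardGeneric("taxonomyOf"))
#' @rdname accessors
#' @export
setMethod("taxonomyOf", "GenomeRecord", function(x) x@taxonomy)
#' @rdname accessors
#' @export
setMethod("taxonomyOf", "Neighborhood", function(x) x@taxonomy)

#' @rdname accessors
#' @export
setGeneric("activeNamespace", function(x) standardGeneric("activeNamespace"))
#' @rdname accessors
#' @export
setMethod("activeNamespace", "NeighborhoodSet", function(x) x@activeNamespace)

#' @rdname accessors
#' @export
setGeneric("activeNamespace<-",
           function(x, value) standardGeneric("activeNamespace<-"))
#' @rdname accessors
#' @export
setReplaceMethod("activeNamespace", "NeighborhoodSet", function(x, value) {
  x@activeNamespace <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("taxonomyRank", function(x) standardGeneric("taxonomyRank"))
#' @rdname accessors
#' @export
setMethod("taxonomyRank", "NeighborhoodSet", function(x) x@taxonomyRank)

#' @rdname accessors
#' @export
setGeneric("taxonomyRank<-",
           function(x, value) standardGeneric("taxonomyRank<-"))
#' @rdname accessors
#' @export
setReplaceMethod("taxonomyRank", "NeighborhoodSet", function(x, value) {
  x@taxonomyRank <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("namespaces", function(x) standardGeneric("namespaces"))
#' @rdname accessors
#' @export
setMethod("namespaces", "GenomeRecord",
          function(x) .namespaceColumns(x@genes))
#' @rdname accessors
#' @export
setMethod("namespaces", "Neighborhood",
          function(x) .namespaceColumns(x@genes))
#' @rdname accessors
#' @export
setMethod("namespaces", "NeighborhoodSet", function(x) {
  sort(unique(unlist(lapply(x, namespaces))))
})

#' @rdname accessors
#' @export
setGeneric("neighborhoodIds", function(x) standardGeneric("neighborhoodIds"))
#' @rdname accessors
#' @export
setMethod("neighborhoodIds", "NeighborhoodSet", function(x) {
  vapply(x, function(n) n@neighborhoodId, character(1))
})

#' @rdname accessors
#' @export
geneLabels <- function(x, namespace, geneId = NULL) {
  gr <- genes(x)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(geneId)) {
    i <- match(geneId, mc$gene_id)
    if (is.na(i)) stop("unknown gene id: ", geneId)
    if (!namespace %in% names(mc)) return(character(0))
    return(as.character(mc[[namespace]][[i]]))
  }
  if (!namespace %in% names(mc))
    return(IRanges::CharacterList(rep(list(character(0)), length(gr))))
  mc[[namespace]]
}

#' @rdname accessors
#' @export
anchorGene <- function(x) {
  stopifnot(is(x, "Neighborhood"))
  gr <- x@genes
  gr[S4Vectors::mcols(gr)$gene_id == x@anchorId]
}

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s' (genome '%s'): %d bp, %d genes\n",
              object@contigId, object@genomeId, object@contigLength,
              length(object@genes)))
  if (nrow(object@taxonomy))
    cat("  taxonomy:", formatTaxonomy(object@taxonomy), "\n")
  ns <- .namespaceColumns(object@genes)
  if (length(ns)) cat("  namespaces:", paste(ns, collapse = ", "), "\n")
})

setMethod("show", "Neighborhood", function(object) {
  cat(sprintf("Neighborhood '%s': %d genes in window [%d, %d] on '%s'%s\n",
              object@neighborhoodId, length(object@genes),
              object@windowStart, object@windowEnd, object@contigId,
              if (object@flipped) " (flipped)" else ""))
  cat("  anchor:", object@anchorId, "\n")
})

setMethod("show", "NeighborhoodSet", function(object) {
  cat(sprintf(
    "NeighborhoodSet: %d neighborhood(s), active namespace '%s', rank '%s'\n",
    length(object), object@activeNamespace, object@taxonomyRank))
  if (length(object)) {
    ids <- neighborhoodIds(object)
    shown <- head(ids, 5L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(ids) > 5L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: score %g, %d aligned pair(s)%s\n",
              object@score, nrow(object@pairs),
              if (object@reversed) ", reversed orientation" else ""))
})

setMethod("show", "ClusterOrdering", function(object) {
  cat(sprintf("ClusterOrdering (%s linkage) over %d neighborhood(s)\n",
              object@linkageMethod, length(object@order)))
  cat("  leaf order:", paste(object@order, collapse = " "), "\n")
})

#' @rdname accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))
#' @rdname accessors
#' @export
setMethod("leafOrder", "ClusterOrdering", function(x) x@order)

#' @rdname accessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))
#' @rdname accessors
#' @export
setMethod("distanceMatrix", "ClusterOrdering", function(x) x@distanceMatrix)

#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
#' @rdname accessors
#' @export
setMethod("alignedPairs", "AlignmentResult", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("isReversed", function(x) standardGeneric("isReversed"))
#' @rdname accessors
#' @export
setMethod("isReversed", "AlignmentResult", function(x) x@reversed)
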