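#' Cluster neighborhoods by the similarity of their gene content
#'
#' Projects every neighborhood onto the set's active namespace (see
#' [labelVector()]), computes all pairwise distances
#' `1 - contextSimilarity()`, and runs agglomerative hierarchical
#' clustering ([stats::hclust()], average linkage by default). The
#' dendrogram leaf order — with a deterministic tie-break that places the
#' subtree containing the lower original index first at every merge — is
#' the clustered display order. Neighborhoods with identical label vectors
#' are at distance 0, merge first, and therefore end up adjacent.
#'
#' @param s a [NeighborhoodSet-class] with at least one neighborhood.
#' @param params an [alignParams()] object.
#' @param linkageMethod agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param anchored require the two anchor genes to be an aligned pair? When
#'   `TRUE`, alignments whose traceback does not pair the anchors score 0
#'   for the similarity. Off by default.
#' @return a [ClusterOrdering-class].
#' @examples
#' ## three neighborhoods where #1 and #3 share every label cluster with
#' ## #1 and #3 adjacent in the leaf order
#' @export
clusterNeighborhoods <- function(s, params = alignParams(),
                                 linkageMethod = "average",
                                 anchored = FALSE) {
  stopifnot(is(s, "NeighborhoodSet"))
  n <- length(s)
  if (n == 0L) stop("nothing to cluster")
  ns <- activeNamespace(s)
  vecs <- lapply(seq_len(n), function(i) labelVector(s[[i]], ns))
  D <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        sim <- .pairSimilarity(vecs[[i]], vecs[[j]], params, anchored)
        D[i, j] <- D[j, i] <- 1 - sim
      }
    }
  }
  ids <- neighborhoodIds(s)
  dimnames(D) <- list(ids, ids)
  ord <- if (n == 1L) 1L else {
    hc <- stats::hclust(stats::as.dist(D), method = linkageMethod)
    .leafOrderDeterministic(hc$merge)
  }
  new("ClusterOrdering", order = as.integer(ord), distanceMatrix = D,
      linkageMethod = linkageMethod)
}

.pairSimilarity <- function(u, v, params, anchored) {
  sim <- suppressWarnings(contextSimilarity(u, v, params))
  if (anchored && sim > 0) {
    res <- localAlign(u, v, params)
    p <- res@pairs
    vAnchor <- if (res@reversed) length(v@entries) + 1L - v@anchorIndex
               else v@anchorIndex
    paired <- any(p[, 1] == u@anchorIndex & p[, 2] == vAnchor)
    if (!paired) sim <- 0
  }
  sim
}

## leaf order from an hclust merge matrix; at every merge the subtree that
## contains the smaller original index goes left
.leafOrderDeterministic <- function(merge) {
  orders <- vector("list", nrow(merge))
  getOrd <- function(x) if (x < 0) -x else orders[[x]]
  for (k in seq_len(nrow(merge))) {
    a <- getOrd(merge[k, 1])
    b <- getOrd(merge[k, 2])
    orders[[k]] <- if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  orders[[nrow(merge)]]
}

#' Reorder a NeighborhoodSet by a clustering result
#'
#' @param s a [NeighborhoodSet-class].
#' @param ordering a [ClusterOrdering-class] from [clusterNeighborhoods()]
#'   (or an integer permutation).
#' @return the reordered [NeighborhoodSet-class].
#' @export
applyOrdering <- function(s, ordering) {
  ord <- if (is(ordering, "ClusterOrdering")) ordering@order else
    as.integer(ordering)
  stopifnot(identical(sort(ord), seq_along(s)))
  neighborhoodSet(as.list(s)[ord],
                  activeNamespace = activeNamespace(s),
                  taxonomyRank = taxonomyRank(s))
}
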