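#' Extract the gene neighborhood around an anchor gene
#'
#' Takes the window `[max(1, anchor_start - windowBp),
#' min(contig_length, anchor_end + windowBp)]` around the anchor gene and
#' returns the genes whose intervals are fully contained in it. Genes that
#' span either window edge are excluded (the edge-exclusion rule); the
#' anchor itself is always retained, even when a truncated window would
#' clip it. Contigs are treated as linear: the window truncates at position
#' 1 and at the contig length and never wraps a circular replicon.
#'
#' @param genome a [GenomeRecord-class].
#' @param anchorId `gene_id` of the anchor gene.
#' @param windowBp window half-width in bp on each side of the anchor
#'   (default 10000, i.e. a +/- 10 kb window).
#' @param neighborhoodId identifier for the result (default
#'   `"<contig>:<anchor>"`).
#' @return a [Neighborhood-class] in source orientation (`flipped = FALSE`),
#'   genes sorted by (start, end).
#' @examples
#' gr <- geneRanges("ctg", c("g1", "g2", "g3"),
#'                  c(100, 900, 5000), c(400, 1200, 5300), c("+", "+", "-"))
#' gn <- genomeRecord("ctg", gr, contigLength = 6000)
#' extractNeighborhood(gn, "g2", windowBp = 1000)
#' @seealso [flipNeighborhood()], [normalizeOrientation()]
#' @export
extractNeighborhood <- function(genome, anchorId, windowBp = 10000,
                                neighborhoodId = NULL) {
  stopifnot(is(genome, "GenomeRecord"), windowBp > 0)
  gr <- genome@genes
  ids <- S4Vectors::mcols(gr)$gene_id
  hit <- which(ids == anchorId)
  if (length(hit) == 0L)
    stop("anchor not found: ", anchorId)
  if (length(hit) > 1L)
    stop("duplicate gene id: ", anchorId)
  a <- gr[hit]
  ws <- max(1L, GenomicRanges::start(a) - as.integer(windowBp))
  we <- min(genome@contigLength, GenomicRanges::end(a) + as.integer(windowBp))
  keep <- GenomicRanges::start(gr) >= ws & GenomicRanges::end(gr) <= we
  keep[hit] <- TRUE  # exclusion rule applies to neighbors only
  out <- gr[keep]
  if (is.null(neighborhoodId))
    neighborhoodId <- paste0(genome@contigId, ":", anchorId)
  new("Neighborhood",
      neighborhoodId = neighborhoodId, anchorId = anchorId, genes = out,
      windowStart = as.integer(ws), windowEnd = as.integer(we),
      flipped = FALSE, genomeId = genome@genomeId,
      contigId = genome@contigId, taxonomy = genome@taxonomy)
}

#' Reverse the display orientation of a neighborhood
#'
#' Reflects every gene within the window (`new_start = windowStart +
#' windowEnd - end`; `new_end = windowStart + windowEnd - start`), toggles
#' strands and the `flipped` bit, and re-sorts the gene list. Flipping is an
#' involution, so the source coordinates are always recoverable.
#'
#' @param n a [Neighborhood-class].
#' @return the flipped [Neighborhood-class].
#' @export
flipNeighborhood <- function(n) {
  stopifnot(is(n, "Neighborhood"))
  gr <- n@genes
  if (length(gr)) {
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    ns <- n@windowStart + n@windowEnd - e
    ne <- n@windowStart + n@windowEnd - s
    GenomicRanges::ranges(gr) <- IRanges::IRanges(start = ns, end = ne)
    str <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(str == "+", "-", "+")
    gr <- gr[order(GenomicRanges::start(gr), GenomicRanges::end(gr))]
  }
  n@genes <- gr
  n@flipped <- !n@flipped
  validObject(n)
  n
}

#' Orient every neighborhood so its anchor is on the plus strand
#'
#' Neighborhoods whose anchor gene lies on the minus strand are flipped
#' (see [flipNeighborhood()]); the rest are returned unchanged. Order is
#' preserved and the operation is idempotent. Consistent anchor orientation
#' is what makes stacked tracks comparable by eye.
#'
#' @param s a [NeighborhoodSet-class].
#' @return the oriented [NeighborhoodSet-class].
#' @export
normalizeOrientation <- function(s) {
  stopifnot(is(s, "NeighborhoodSet"))
  for (i in seq_along(s)) {
    n <- s[[i]]
    astr <- as.character(GenomicRanges::strand(anchorGene(n)))
    if (astr == "-") s[[i]] <- flipNeighborhood(n)
  }
  s
}

#' Search products and annotation labels for a term
#'
#' Case-insensitive substring search over every gene's product description
#' and every label in every annotation namespace, across the whole set. An
#' empty term matches nothing.
#'
#' @param s a [NeighborhoodSet-class].
#' @param term search term (fixed substring, not a regular expression).
#' @return data.frame with columns `neighborhood_id`, `gene_id`, one row per
#'   matching gene, in set/gene order.
#' @examples
#' ## searching "flagellar" finds e.g. FliF and FliG products but not
#' ## hypothetical proteins
#' @export
searchTerm <- function(s, term) {
  stopifnot(is(s, "NeighborhoodSet"), is.character(term), length(term) == 1L)
  empty <- data.frame(neighborhood_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(term)) return(empty)
  needle <- tolower(term)
  rows <- lapply(seq_along(s), function(i) {
    n <- s[[i]]
    gr <- n@genes
    if (!length(gr)) return(NULL)
    mc <- S4Vectors::mcols(gr)
    hit <- grepl(needle, tolower(mc$product), fixed = TRUE)
    for (ns in .namespaceColumns(gr)) {
      labHit <- vapply(mc[[ns]], function(labs)
        any(grepl(needle, tolower(labs), fixed = TRUE)), logical(1))
      hit <- hit | labHit
    }
    if (!any(hit)) return(NULL)
    data.frame(neighborhood_id = n@neighborhoodId,
               gene_id = mc$gene_id[hit], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
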