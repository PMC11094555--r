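#' Alignment scoring parameters
#'
#' Bundles the scoring scheme for the gene-order local alignment. Two gene
#' positions *match* when their annotation label sets share at least one
#' label; positions with disjoint sets, or where either set is empty,
#' *mismatch*. Unannotated genes therefore never match anything — including
#' each other — which keeps runs of hypothetical proteins from inflating
#' similarity.
#'
#' @param match score for a matching pair (must be > 0; default `1`).
#' @param mismatch score for a mismatching pair (<= match; default `-1`).
#' @param gap score per skipped gene (<= 0; default `-1`).
#' @param tryReverse also align against the reversed second vector and keep
#'   the better orientation (default `TRUE`); this is what lets inverted
#'   gene clusters align.
#' @return a validated list of class `"AlignParams"`.
#' @seealso [localAlign()], [contextSimilarity()], [clusterNeighborhoods()]
#' @export
alignParams <- function(match = 1, mismatch = -1, gap = -1,
                        tryReverse = TRUE) {
  stopifnot(match > 0, gap <= 0, mismatch <= match,
            is.logical(tryReverse), length(tryReverse) == 1L)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 tryReverse = tryReverse),
            class = "AlignParams")
}

#' Project a neighborhood onto one annotation namespace
#'
#' Builds the [LabelVector-class] that the alignment operates on: one label
#' set per gene in display order (empty set where the gene carries no label
#' in that namespace), with the anchor's position recorded. Switching
#' namespace changes the entries but never the length or the anchor index.
#'
#' @param n a [Neighborhood-class].
#' @param namespace annotation namespace name (e.g. `"Pfam"`).
#' @return a [LabelVector-class].
#' @export
labelVector <- function(n, namespace) {
  stopifnot(is(n, "Neighborhood"))
  gr <- n@genes
  entries <- as.list(geneLabels(n, namespace))
  entries <- lapply(entries, as.character)
  ai <- match(n@anchorId, S4Vectors::mcols(gr)$gene_id)
  new("LabelVector", entries = entries, anchorIndex = as.integer(ai),
      sourceId = n@neighborhoodId)
}

## logical match matrix: M[i, j] = TRUE iff entries intersect (both non-empty)
.matchMatrix <- function(u, v) {
  n <- length(u)
  m <- length(v)
  M <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    ui <- u[[i]]
    if (!length(ui)) next
    for (j in seq_len(m)) {
      vj <- v[[j]]
      if (length(vj) && any(ui %in% vj)) M[i, j] <- TRUE
    }
  }
  M
}

.asEntries <- function(x) {
  if (is(x, "LabelVector")) x@entries
  else if (is.list(x)) lapply(x, as.character)
  else stop("expected a LabelVector or a list of character vectors")
}

#' Local alignment of two annotation-label vectors
#'
#' A Smith-Waterman-style local alignment applied to gene neighborhoods:
#' the "sequences" are ordered per-gene annotation label sets and two
#' positions match when their sets intersect (see [alignParams()]). Cells
#' are floored at zero, so the score is always >= 0. The traceback starts
#' at the best-scoring cell (ties: smallest position pair) and prefers
#' diagonal over up over left, making the reported pairs deterministic.
#' With `tryReverse`, `v` is also aligned in reversed order and the better
#' orientation is reported (`isReversed()`); on a score tie the forward
#' orientation wins. When the result is reversed, the `v` column of
#' [alignedPairs()] indexes positions of the reversed vector.
#'
#' @param u,v [LabelVector-class] objects (or plain lists of character
#'   vectors). Must be non-empty.
#' @param params an [alignParams()] object.
#' @return an [AlignmentResult-class].
#' @examples
#' u <- list("A", "B", "C", "D")
#' v <- list("X", "B", "C", "Y")
#' localAlign(u, v)  # score 2 via the B-C block
#' @export
localAlign <- function(u, v, params = alignParams()) {
  eu <- .asEntries(u)
  ev <- .asEntries(v)
  if (!length(eu) || !length(ev)) stop("empty neighborhood")
  fwd <- .sw_align_core(.matchMatrix(eu, ev), params$match, params$mismatch,
                        params$gap)
  score <- fwd$score
  pairs <- fwd$pairs
  reversed <- FALSE
  if (isTRUE(params$tryReverse)) {
    rev <- .sw_align_core(.matchMatrix(eu, base::rev(ev)), params$match,
                          params$mismatch, params$gap)
    if (rev$score > fwd$score) {
      score <- rev$score
      pairs <- rev$pairs
      reversed <- TRUE
    }
  }
  colnames(pairs) <- c("u", "v")
  new("AlignmentResult", score = score, pairs = pairs, reversed = reversed)
}

#' Similarity of two gene neighborhoods
#'
#' Normalizes the local alignment score by the smaller of the two
#' self-alignment scores (computed without the reversed orientation), so
#' the result is scale-free in neighborhood length and bounded in
#' `[0, 1]`: a neighborhood is perfectly similar to itself, and fully
#' disjoint neighborhoods score 0. When both vectors are entirely
#' unannotated the similarity is defined as 0 (with a warning).
#'
#' @inheritParams localAlign
#' @return a number in `[0, 1]`, symmetric in `u` and `v`.
#' @export
contextSimilarity <- function(u, v, params = alignParams()) {
  eu <- .asEntries(u)
  ev <- .asEntries(v)
  if (!length(eu) || !length(ev)) stop("empty neighborhood")
  selfParams <- alignParams(params$match, params$mismatch, params$gap,
                            tryReverse = FALSE)
  su <- localAlign(eu, eu, selfParams)@score
  sv <- localAlign(ev, ev, selfParams)@score
  denom <- min(su, sv)
  if (denom <= 0) {
    warning("both neighborhoods are unannotated in this namespace; ",
            "similarity defined as 0")
    return(0)
  }
  s <- localAlign(eu, ev, params)@score / denom
  min(max(s, 0), 1)
}
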