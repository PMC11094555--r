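## Exhaustive reference for the local alignment score, used to validate the
## dynamic program. Kept deliberately independent of the DP: instead of a
## score matrix recurrence it enumerates every possible local alignment
## directly. A local alignment of u and v is a chain of aligned position
## pairs (i_1, j_1) < ... < (i_k, j_k), strictly increasing in both
## coordinates; its score is the sum of the pair scores (match when the
## label sets intersect, else mismatch) plus the gap score for every
## position skipped strictly inside the chain:
##   gaps = (i_k - i_1 + 1 - k) + (j_k - j_1 + 1 - k).
## Positions outside the chain ends are free (that is what makes it local),
## and the empty chain scores 0. Feasible only for short vectors: the chain
## count is sum_k C(|u|, k) * C(|v|, k).

.subsetCache <- new.env(parent = emptyenv())

.subsets <- function(n, k) {
  key <- paste(n, k)
  if (is.null(.subsetCache[[key]]))
    .subsetCache[[key]] <- t(utils::combn(n, k))
  .subsetCache[[key]]
}

#' Exhaustive local alignment score (reference implementation)
#'
#' Computes the best local alignment score of two annotation-label vectors
#' by enumerating all chains of aligned position pairs, rather than by
#' dynamic programming. Exponential in vector length; intended for
#' validating [localAlign()] on short vectors (lengths up to ~8).
#'
#' @inheritParams localAlign
#' @return the best local alignment score (>= 0).
#' @export
alignScoreExhaustive <- function(u, v, params = alignParams()) {
  eu <- .asEntries(u)
  ev <- .asEntries(v)
  if (!length(eu) || !length(ev)) stop("empty neighborhood")
  best <- .chainScoreMax(eu, ev, params)
  if (isTRUE(params$tryReverse))
    best <- max(best, .chainScoreMax(eu, base::rev(ev), params))
  best
}

.chainScoreMax <- function(eu, ev, params) {
  n <- length(eu)
  m <- length(ev)
  S <- ifelse(.matchMatrix(eu, ev), params$match, params$mismatch)
  best <- 0
  for (k in seq_len(min(n, m))) {
    SU <- .subsets(n, k)
    SV <- .subsets(m, k)
    tot <- matrix(0, nrow(SU), nrow(SV))
    for (t in seq_len(k))
      tot <- tot + S[SU[, t], SV[, t], drop = FALSE]
    gu <- SU[, k] - SU[, 1] + 1 - k
    gv <- SV[, k] - SV[, 1] + 1 - k
    tot <- tot + params$gap * outer(gu, gv, "+")
    best <- max(best, max(tot))
  }
  best
}
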