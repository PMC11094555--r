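#' Hit tables
#'
#' Homology search hits are carried as plain data.frames with one row per
#' hit and columns `query_id`, `subject_id`, `pct_identity`, `evalue`,
#' `bitscore`, `q_cov`, `s_cov` (query-to-subject and subject-to-query
#' alignment coverage, percent) and `subject_taxonomy` (GTDB-style string,
#' possibly `""`). [readHits()] produces this layout from 12-column tabular
#' search output; [generateHits()] produces synthetic tables.
#'
#' @name hit-tables
NULL

.HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "evalue",
                  "bitscore", "q_cov", "s_cov", "subject_taxonomy")

.checkHitTable <- function(hits) {
  missing <- setdiff(.HIT_COLUMNS, names(hits))
  if (length(missing))
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  invisible(hits)
}

#' Filter homology hits by E-value, identity and bidirectional coverage
#'
#' Retains hits with `evalue <= maxEvalue`, `pct_identity >= minIdentity`
#' and both coverages `>= minCoverage`, preserving input order. The
#' defaults are the thresholds used to transfer annotations between
#' homologous protein clusters: E-value <= 1e-5, identity >= 30% and
#' query-to-subject and subject-to-query coverage >= 70%.
#'
#' @param hits hit data.frame (see [hit-tables]).
#' @param maxEvalue maximum E-value (default `1e-5`).
#' @param minIdentity minimum percent identity (default `30`).
#' @param minCoverage minimum percent coverage, applied to both `q_cov` and
#'   `s_cov` (default `70`).
#' @return the retained rows, input order preserved (possibly zero rows).
#' @export
filterHits <- function(hits, maxEvalue = 1e-5, minIdentity = 30,
                       minCoverage = 70) {
  .checkHitTable(hits)
  keep <- hits$evalue <= maxEvalue &
    hits$pct_identity >= minIdentity &
    hits$q_cov >= minCoverage &
    hits$s_cov >= minCoverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-N hits ranked by E-value
#'
#' Ties on E-value are broken by larger bitscore, then by input order; the
#' result is sorted ascending by (evalue, -bitscore, input index).
#'
#' @param hits hit data.frame (see [hit-tables]).
#' @param n number of hits to keep (>= 1); `n >=` the number of hits
#'   returns all of them, sorted.
#' @return the selected rows in rank order.
#' @export
selectTopByEvalue <- function(hits, n) {
  .checkHitTable(hits)
  stopifnot(length(n) == 1L, n >= 1)
  o <- order(hits$evalue, -hits$bitscore, seq_len(nrow(hits)))
  out <- hits[utils::head(o, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hits from a taxonomic lineage
#'
#' Keeps hits whose subject taxonomy carries the given name at the given
#' rank (exact, case-insensitive name match), e.g. all hits in the genus
#' Methanosarcina. Input order is preserved.
#'
#' @param hits hit data.frame (see [hit-tables]).
#' @param rank canonical rank name (domain, phylum, class, order, family,
#'   genus, species).
#' @param name taxon name to match.
#' @return the matching rows.
#' @export
selectByTaxonomy <- function(hits, rank, name) {
  .checkHitTable(hits)
  if (!rank %in% .CANONICAL_RANKS)
    stop("not a canonical rank name: ", rank)
  keep <- vapply(hits$subject_taxonomy, function(s) {
    tax <- parseTaxonomy(if (is.na(s)) "" else s)
    tolower(.taxonomyName(tax, rank)) == tolower(name)
  }, logical(1), USE.NAMES = FALSE)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
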