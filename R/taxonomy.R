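.RANK_PREFIXES <- c(d = "domain", p = "phylum", c = "class", o = "order",
                    f = "family", g = "genus", s = "species")

#' Parse a GTDB-style taxonomy string
#'
#' GTDB lineage strings use single-letter rank prefixes joined by
#' semicolons, e.g. `"d__Archaea;p__Halobacteriota;g__Methanosarcina"`.
#' Empty names (`"g__"`) are allowed and dropped unless `keepEmpty = TRUE`.
#'
#' @param s a single taxonomy string; `""` or `NA` yield an empty taxonomy.
#' @param keepEmpty keep ranks with empty names? Default `FALSE`.
#' @return data.frame with columns `rank` and `name`, ranks in canonical
#'   order (domain, phylum, class, order, family, genus, species).
#' @examples
#' parseTaxonomy("d__Archaea;g__Methanosarcina")
#' @export
parseTaxonomy <- function(s, keepEmpty = FALSE) {
  if (length(s) != 1L) stop("parseTaxonomy() expects a single string")
  if (is.na(s) || !nzchar(trimws(s))) return(.emptyTaxonomy())
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  pref <- sub("__.*$", "", parts)
  bad <- !(pref %in% names(.RANK_PREFIXES)) | !grepl("^[a-z]__", parts)
  if (any(bad))
    stop("unknown taxonomy rank prefix: ", paste(parts[bad], collapse = ", "))
  tax <- data.frame(rank = unname(.RANK_PREFIXES[pref]),
                    name = sub("^[a-z]__", "", parts),
                    stringsAsFactors = FALSE)
  if (!keepEmpty) tax <- tax[nzchar(tax$name), , drop = FALSE]
  tax <- tax[order(match(tax$rank, .CANONICAL_RANKS)), , drop = FALSE]
  rownames(tax) <- NULL
  msg <- .validTaxonomy(tax)
  if (!is.null(msg)) stop(msg)
  tax
}

#' Format a taxonomy data.frame as a GTDB-style string
#'
#' Inverse of [parseTaxonomy()] (up to empty ranks).
#'
#' @param tax data.frame with columns `rank`, `name`.
#' @return a single prefixed, semicolon-joined string; `""` when empty.
#' @export
formatTaxonomy <- function(tax) {
  if (is.null(tax) || nrow(tax) == 0L) return("")
  pref <- names(.RANK_PREFIXES)[match(tax$rank, .RANK_PREFIXES)]
  paste0(pref, "__", tax$name, collapse = ";")
}

## name at a rank, or "" if absent
.taxonomyName <- function(tax, rank) {
  i <- match(rank, tax$rank)
  if (is.na(i)) "" else tax$name[i]
}
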