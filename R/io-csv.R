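## The package's canonical CSV interchange dialect: one row per gene,
## grouped by neighborhood. Fixed leading columns, then one column per
## annotation namespace (lowercased name; multiple labels comma-joined
## inside the quoted cell), then protein_seq when present.
.CSV_FIXED <- c("neighborhood_id", "genome_id", "taxonomy", "contig_id",
                "gene_id", "start", "end", "strand", "product", "is_anchor")
.CSV_CANONICAL_NS <- c(kegg = "KEGG", pfam = "Pfam", tigrfam = "TIGRFAM")

.nsToColumn <- function(ns) {
  hit <- names(.CSV_CANONICAL_NS)[match(ns, .CSV_CANONICAL_NS)]
  ifelse(is.na(hit), tolower(ns), hit)
}

.columnToNs <- function(col) {
  hit <- .CSV_CANONICAL_NS[col]
  ifelse(is.na(hit), col, hit)
}

#' Write a NeighborhoodSet as CSV
#'
#' One row per gene in display order, grouped by neighborhood. Columns:
#' `neighborhood_id, genome_id, taxonomy, contig_id, gene_id, start, end,
#' strand, product, is_anchor`, then one column per annotation namespace
#' (`kegg`, `pfam`, `tigrfam` always present, custom namespaces appended;
#' multiple labels are comma-joined within the cell), then `protein_seq`
#' when any gene carries one. Taxonomy is a GTDB-style prefixed string.
#'
#' @param s a [NeighborhoodSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readNeighborhoodCsv()]
#' @export
writeNeighborhoodCsv <- function(s, path) {
  stopifnot(is(s, "NeighborhoodSet"))
  extraNs <- setdiff(namespaces(s), .CSV_CANONICAL_NS)
  nsCols <- c(names(.CSV_CANONICAL_NS), sort(.nsToColumn(extraNs)))
  nsNames <- .columnToNs(nsCols)
  hasProt <- any(vapply(s, function(n)
    "protein_seq" %in% names(S4Vectors::mcols(n@genes)), logical(1)))
  rows <- lapply(seq_along(s), function(i) {
    n <- s[[i]]
    gr <- n@genes
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(
      neighborhood_id = n@neighborhoodId,
      genome_id = n@genomeId,
      taxonomy = formatTaxonomy(n@taxonomy),
      contig_id = n@contigId,
      gene_id = mc$gene_id,
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      product = mc$product,
      is_anchor = as.integer(mc$gene_id == n@anchorId),
      stringsAsFactors = FALSE)
    for (k in seq_along(nsCols)) {
      ns <- nsNames[k]
      df[[nsCols[k]]] <- if (ns %in% names(mc))
        vapply(as.list(mc[[ns]]), paste, character(1), collapse = ",")
      else ""
    }
    if (hasProt) {
      ps <- if ("protein_seq" %in% names(mc)) mc$protein_seq else
        rep(NA_character_, length(gr))
      df$protein_seq <- ifelse(is.na(ps), "", ps)
    }
    df
  })
  df <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c(.CSV_FIXED, nsCols)
    stats::setNames(
      as.data.frame(rep(list(character(0)), length(cols))), cols)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a NeighborhoodSet from CSV
#'
#' Parses the dialect written by [writeNeighborhoodCsv()]: rows are grouped
#' by `neighborhood_id` preserving file order, each group must mark exactly
#' one `is_anchor = 1` row, and every column after `is_anchor` other than
#' `protein_seq` is treated as an annotation namespace (`kegg`/`pfam`/
#' `tigrfam` map to the KEGG/Pfam/TIGRFAM namespaces). Window bounds are
#' not serialized; they are reconstructed as the gene span and neighborhoods
#' read back in source orientation (`flipped = FALSE`).
#'
#' @param path CSV file.
#' @param activeNamespace namespace for the returned set; default: the
#'   first namespace column with any labels, else `"KEGG"`.
#' @return a [NeighborhoodSet-class].
#' @export
readNeighborhoodCsv <- function(path, activeNamespace = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(.CSV_FIXED, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  nsCols <- setdiff(names(df)[seq(match("is_anchor", names(df)) + 1L,
                                  length.out = max(0L, ncol(df) -
                                    match("is_anchor", names(df))))],
                    "protein_seq")
  if (is.null(activeNamespace)) {
    withLabels <- nsCols[vapply(nsCols, function(cl)
      any(nzchar(df[[cl]])), logical(1))]
    activeNamespace <- if (length(withLabels))
      unname(.columnToNs(withLabels[1])) else "KEGG"
  }
  if (nrow(df) == 0L)
    return(neighborhoodSet(activeNamespace = activeNamespace))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop("non-integer start/end coordinates in ", path)
  groups <- split(seq_len(nrow(df)), factor(df$neighborhood_id,
                                            levels = unique(df$neighborhood_id)))
  nbhs <- lapply(names(groups), function(nid) {
    idx <- groups[[nid]]
    sub <- df[idx, , drop = FALSE]
    anchors <- sub$gene_id[sub$is_anchor == "1"]
    if (length(anchors) != 1L)
      stop("neighborhood '", nid, "' must have exactly one anchor row (has ",
           length(anchors), ")")
    labels <- list()
    for (cl in nsCols) {
      vals <- lapply(strsplit(sub[[cl]], ",", fixed = TRUE),
                     function(x) trimws(x[nzchar(trimws(x))]))
      if (any(lengths(vals) > 0)) labels[[unname(.columnToNs(cl))]] <- vals
    }
    pseq <- if ("protein_seq" %in% names(sub)) {
      ps <- sub$protein_seq
      if (any(nzchar(ps))) ifelse(nzchar(ps), ps, NA_character_) else NULL
    } else NULL
    gr <- geneRanges(sub$contig_id[1], sub$gene_id, sub$start, sub$end,
                     sub$strand, sub$product, labels, proteinSeq = pseq)
    neighborhood(nid, anchors, gr,
                 genomeId = sub$genome_id[1], contigId = sub$contig_id[1],
                 taxonomy = parseTaxonomy(sub$taxonomy[1]))
  })
  neighborhoodSet(nbhs, activeNamespace = activeNamespace)
}
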