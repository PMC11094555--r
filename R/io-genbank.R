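#' Read annotated genomes from a GenBank flat file
#'
#' A purpose-built parser for the feature-table subset this package needs:
#' one [GenomeRecord-class] per `LOCUS`, CDS features only. Products come
#' from `/product`, gene ids from `/locus_tag` (falling back to
#' `/protein_id`, `/gene`, then `<contig>:<start>-<end>`), annotation
#' labels from `/db_xref` entries with `Pfam:`, `KEGG:`, `TIGR:` or
#' `TIGRFAM:` prefixes, and amino-acid sequences from `/translation`.
#' `complement(start..end)` locations map to the minus strand; compound
#' `join(...)`/`order(...)` locations collapse to their outermost span with
#' a warning. Nucleotide sequence under `ORIGIN` is skipped.
#'
#' @param path GenBank flat file (one or more records).
#' @return list of [GenomeRecord-class] in file order.
#' @seealso [readGff3()], [writeGenBank()]
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "LOCUS"))
  if (!length(starts)) stop("no LOCUS record found in ", path)
  ends <- which(startsWith(lines, "//"))
  lapply(seq_along(starts), function(k) {
    from <- starts[k]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    .parseGenBankRecord(lines[from:to], path)
  })
}

.parseGenBankRecord <- function(rl, path) {
  toks <- strsplit(trimws(rl[1]), "\\s+")[[1]]
  locusName <- if (length(toks) >= 2L) toks[2] else
    stop("malformed LOCUS line in ", path)
  bpAt <- which(toks == "bp")[1]
  if (is.na(bpAt) || bpAt < 3L)
    stop("malformed record '", locusName, "': LOCUS line lacks a bp length")
  contigLength <- suppressWarnings(as.integer(toks[bpAt - 1L]))
  if (is.na(contigLength))
    stop("malformed record '", locusName, "': unreadable sequence length")
  featAt <- which(startsWith(rl, "FEATURES"))[1]
  if (is.na(featAt))
    stop("malformed record '", locusName, "': no FEATURES table")
  stopAt <- which(startsWith(rl, "ORIGIN") | startsWith(rl, "CONTIG") |
                  startsWith(rl, "BASE COUNT") | startsWith(rl, "//"))
  stopAt <- c(stopAt[stopAt > featAt], length(rl) + 1L)[1]
  feat <- rl[seq(featAt + 1L, stopAt - 1L)]
  feat <- feat[nzchar(trimws(feat))]
  # a feature header has its key at column 6; qualifier/continuation lines
  # are indented to column 22
  isHeader <- grepl("^ {5}\\S", feat)
  if (length(feat) && !isHeader[1])
    stop("malformed record '", locusName, "': feature table does not start ",
         "with a feature key")
  grp <- cumsum(isHeader)
  genes <- list()
  for (g in split(feat, grp)) {
    header <- g[1]
    key <- sub("^\\s+", "", substr(header, 1, 20))
    key <- sub("\\s.*$", "", key)
    rest <- trimws(substring(header, 21))
    body <- if (length(g) > 1L) trimws(g[-1]) else character(0)
    # location may continue until the first qualifier line
    qualAt <- which(startsWith(body, "/"))
    locCont <- if (length(qualAt)) body[seq_len(qualAt[1] - 1L)] else body
    location <- paste0(rest, paste(locCont, collapse = ""))
    quals <- if (length(qualAt)) body[seq(qualAt[1], length(body))] else
      character(0)
    if (key != "CDS") next
    genes[[length(genes) + 1L]] <-
      .parseGenBankCds(location, quals, locusName)
  }
  if (length(genes)) {
    ids <- vapply(genes, `[[`, character(1), "gene_id")
    fallback <- !nzchar(ids)
    if (any(fallback))
      ids[fallback] <- vapply(genes[fallback], function(g)
        paste0(locusName, ":", g$start, "-", g$end), character(1))
    gr <- geneRanges(
      locusName, ids,
      vapply(genes, `[[`, integer(1), "start"),
      vapply(genes, `[[`, integer(1), "end"),
      vapply(genes, `[[`, character(1), "strand"),
      vapply(genes, `[[`, character(1), "product"),
      labels = list(KEGG = lapply(genes, `[[`, "KEGG"),
                    Pfam = lapply(genes, `[[`, "Pfam"),
                    TIGRFAM = lapply(genes, `[[`, "TIGRFAM")),
      proteinSeq = vapply(genes, `[[`, character(1), "protein_seq"))
    mc <- S4Vectors::mcols(gr)
    for (ns in c("KEGG", "Pfam", "TIGRFAM"))
      if (ns %in% names(mc) && !any(lengths(mc[[ns]]) > 0)) mc[[ns]] <- NULL
    if (all(is.na(mc$protein_seq))) mc$protein_seq <- NULL
    S4Vectors::mcols(gr) <- mc
  } else {
    gr <- geneRanges(locusName, character(0), integer(0), integer(0),
                     character(0))
  }
  genomeRecord(locusName, gr, contigLength = contigLength,
               genomeId = locusName)
}

.parseGenBankCds <- function(location, quals, locusName) {
  loc <- gsub("[<> ]", "", location)
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  if (grepl("join|order", loc))
    warning("compound location in '", locusName,
            "' collapsed to its outer span: ", location)
  nums <- suppressWarnings(as.integer(
    regmatches(loc, gregexpr("[0-9]+", loc))[[1]]))
  if (length(nums) < 1L || anyNA(nums))
    stop("malformed record '", locusName, "': unparseable CDS location '",
         location, "'")
  # fold multi-line qualifiers into single strings
  folded <- character(0)
  for (q in quals) {
    if (startsWith(q, "/")) folded <- c(folded, q)
    else if (length(folded))
      folded[length(folded)] <- paste0(folded[length(folded)],
        if (grepl("^[A-Z]+$", q)) "" else " ", q)
  }
  getq <- function(name) {
    pat <- paste0("^/", name, "=")
    hits <- folded[grepl(pat, folded)]
    vals <- sub(pat, "", hits)
    gsub("^\"|\"$", "", vals)
  }
  xrefs <- getq("db_xref")
  labs <- .xrefLabels(xrefs)
  transl <- getq("translation")
  transl <- if (length(transl)) gsub("\\s", "", transl[1]) else NA_character_
  idCandidates <- c(getq("locus_tag"), getq("protein_id"), getq("gene"))
  gid <- if (length(idCandidates)) idCandidates[1] else ""
  prod <- getq("product")
  list(start = min(nums), end = max(nums), strand = strand,
       gene_id = gid, product = if (length(prod)) prod[1] else "",
       KEGG = labs$KEGG, Pfam = labs$Pfam, TIGRFAM = labs$TIGRFAM,
       protein_seq = transl)
}

.gbWrap <- function(text, indent = 21L, width = 79L) {
  avail <- width - indent
  out <- character(0)
  while (nchar(text) > avail) {
    cut <- avail
    sp <- gregexpr(" ", substr(text, 1, avail + 1L))[[1]]
    sp <- sp[sp > 0]
    if (length(sp)) cut <- max(sp) - 1L
    out <- c(out, substr(text, 1, cut))
    text <- sub("^ +", "", substring(text, cut + 1L))
  }
  paste0(strrep(" ", indent), c(out, text))
}

#' Write GenomeRecords as a GenBank flat file
#'
#' Emits the feature-table subset that [readGenBank()] parses: a `LOCUS`
#' line with the contig length, a `source` feature, and one CDS per gene
#' with `/locus_tag`, `/product`, per-label `/db_xref` qualifiers and
#' `/translation` when a protein sequence is stored. No nucleotide
#' sequence is written.
#'
#' @param records a [GenomeRecord-class] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(records, path) {
  if (is(records, "GenomeRecord")) records <- list(records)
  out <- character(0)
  for (rec in records) {
    out <- c(out,
      sprintf("LOCUS       %-17s %d bp    DNA     linear   BCT",
              rec@contigId, rec@contigLength),
      sprintf("DEFINITION  %s.", rec@genomeId),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", rec@contigLength))
    gr <- rec@genes
    mc <- S4Vectors::mcols(gr)
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i]
      e <- GenomicRanges::end(gr)[i]
      loc <- if (as.character(GenomicRanges::strand(gr))[i] == "-")
        sprintf("complement(%d..%d)", s, e) else sprintf("%d..%d", s, e)
      out <- c(out, sprintf("     CDS             %s", loc),
               .gbWrap(sprintf("/locus_tag=\"%s\"", mc$gene_id[i])))
      if (nzchar(mc$product[i]))
        out <- c(out, .gbWrap(sprintf("/product=\"%s\"", mc$product[i])))
      for (ns in .namespaceColumns(gr)) {
        pref <- switch(ns, KEGG = "KEGG", Pfam = "Pfam", TIGRFAM = "TIGR",
                       ns)
        for (lab in mc[[ns]][[i]])
          out <- c(out, .gbWrap(sprintf("/db_xref=\"%s:%s\"", pref, lab)))
      }
      if ("protein_seq" %in% names(mc) && !is.na(mc$protein_seq[i]))
        out <- c(out, .gbWrap(sprintf("/translation=\"%s\"",
                                      mc$protein_seq[i])))
    }
    out <- c(out, "ORIGIN", "//")
  }
  writeLines(out, path)
  invisible(path)
}
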