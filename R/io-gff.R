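## db_xref / Dbxref prefix -> annotation namespace
.XREF_NAMESPACES <- c(Pfam = "Pfam", PFAM = "Pfam", KEGG = "KEGG",
                      TIGR = "TIGRFAM", TIGRFAM = "TIGRFAM")
## lowercase GFF attribute -> annotation namespace
.ATTR_NAMESPACES <- c(kegg = "KEGG", pfam = "Pfam", tigrfam = "TIGRFAM")

.splitLabels <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  x <- as.character(unlist(x, use.names = FALSE))
  x <- x[!is.na(x)]
  out <- unlist(strsplit(x, ",", fixed = TRUE), use.names = FALSE)
  trimmed <- trimws(out)
  trimmed[nzchar(trimmed)]
}

.xrefLabels <- function(xrefs) {
  labs <- list(KEGG = character(0), Pfam = character(0),
               TIGRFAM = character(0))
  for (x in .splitLabels(xrefs)) {
    pref <- sub(":.*$", "", x)
    if (pref %in% names(.XREF_NAMESPACES)) {
      ns <- .XREF_NAMESPACES[[pref]]
      labs[[ns]] <- c(labs[[ns]], sub("^[^:]*:", "", x))
    }
  }
  labs
}

#' Read annotated genomes from a GFF3 file
#'
#' Ingests CDS features (other feature types are skipped with a message)
#' into one [GenomeRecord-class] per contig. Coordinates stay 1-based
#' inclusive. Gene ids come from the `ID` attribute, falling back to
#' `locus_tag`, then `<contig>:<start>-<end>`. Products come from the
#' `product` attribute; annotation labels from `Dbxref`/`Ontology_term`
#' entries with `Pfam:`, `KEGG:` or `TIGR:` prefixes and from custom
#' `kegg=`/`pfam=`/`tigrfam=` attributes (comma-separated). Contig lengths
#' come from `##sequence-region` pragmas; when a contig has none, the
#' largest feature end is used with a warning.
#'
#' @param path GFF3 file.
#' @param fastaPath optional protein FASTA whose names match gene ids;
#'   matching sequences are stored as `protein_seq`.
#' @param genomeId genome identifier for all records (default: file name
#'   without extension).
#' @return list of [GenomeRecord-class], one per contig, in file order.
#' @seealso [readGenBank()], [writeGff3()]
#' @export
readGff3 <- function(path, fastaPath = NULL, genomeId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  fastaAt <- which(lines == "##FASTA")[1]
  scope <- if (is.na(fastaAt)) seq_along(lines) else seq_len(fastaAt - 1L)
  body <- scope[!startsWith(lines[scope], "#") & nzchar(trimws(lines[scope]))]
  nFields <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                    integer(1))
  if (any(nFields != 9L))
    stop("GFF3 parse error at line ", body[which(nFields != 9L)[1]],
         ": expected 9 tab-separated fields")
  seqreg <- lines[startsWith(lines, "##sequence-region")]
  regLen <- integer(0)
  if (length(seqreg)) {
    toks <- strsplit(trimws(sub("^##sequence-region", "", seqreg)), "\\s+")
    ok <- lengths(toks) >= 3L
    regLen <- vapply(toks[ok], function(t) as.integer(t[3]), integer(1))
    names(regLen) <- vapply(toks[ok], `[`, character(1), 1L)
  }
  df <- as.data.frame(rtracklayer::readGFF(path))
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]*$", "", basename(path))
  nonCds <- sum(df$type != "CDS")
  if (nonCds > 0)
    message("skipping ", nonCds, " non-CDS feature(s)")
  df <- df[df$type == "CDS", , drop = FALSE]
  prot <- NULL
  if (!is.null(fastaPath)) {
    aa <- Biostrings::readAAStringSet(fastaPath)
    names(aa) <- sub("\\s.*$", "", names(aa))
    prot <- aa
  }
  contigs <- unique(as.character(df$seqid))
  if (!length(contigs) && length(regLen)) contigs <- names(regLen)
  lapply(contigs, function(ctg) {
    sub <- df[as.character(df$seqid) == ctg, , drop = FALSE]
    ids <- if ("ID" %in% names(sub)) as.character(sub$ID) else
      rep(NA_character_, nrow(sub))
    if ("locus_tag" %in% names(sub)) {
      lt <- as.character(sub$locus_tag)
      ids[is.na(ids)] <- lt[is.na(ids)]
    }
    fallback <- paste0(ctg, ":", sub$start, "-", sub$end)
    ids[is.na(ids) | !nzchar(ids)] <- fallback[is.na(ids) | !nzchar(ids)]
    product <- if ("product" %in% names(sub)) {
      p <- as.character(sub$product)
      ifelse(is.na(p), "", p)
    } else rep("", nrow(sub))
    labels <- list(KEGG = vector("list", nrow(sub)),
                   Pfam = vector("list", nrow(sub)),
                   TIGRFAM = vector("list", nrow(sub)))
    for (r in seq_len(nrow(sub))) {
      xr <- character(0)
      for (col in c("Dbxref", "Ontology_term"))
        if (col %in% names(sub)) xr <- c(xr, .splitLabels(sub[[col]][r]))
      fromXref <- .xrefLabels(xr)
      for (ns in names(labels)) {
        vals <- fromXref[[ns]]
        attrCol <- names(.ATTR_NAMESPACES)[.ATTR_NAMESPACES == ns]
        if (attrCol %in% names(sub))
          vals <- c(vals, .splitLabels(sub[[attrCol]][r]))
        labels[[ns]][[r]] <- unique(vals)
      }
    }
    labels <- labels[vapply(labels, function(l)
      any(lengths(l) > 0), logical(1))]
    pseq <- NULL
    if (!is.null(prot)) {
      pseq <- rep(NA_character_, length(ids))
      hitIdx <- match(ids, names(prot))
      pseq[!is.na(hitIdx)] <- as.character(prot[hitIdx[!is.na(hitIdx)]])
    }
    gr <- geneRanges(ctg, ids, sub$start, sub$end,
                     as.character(sub$strand), product, labels,
                     proteinSeq = pseq)
    len <- regLen[ctg]
    if (is.na(len) || is.null(len) || !length(len)) {
      len <- if (nrow(sub)) max(sub$end) else 1L
      warning("no ##sequence-region for contig '", ctg,
              "'; inferring length ", len)
    }
    genomeRecord(ctg, gr, contigLength = len, genomeId = genomeId)
  })
}

.gffEscape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

#' Write GenomeRecords to a GFF3 file
#'
#' Emits CDS rows with `ID`, `product` and per-namespace
#' `kegg=`/`pfam=`/`tigrfam=` attributes, plus `##sequence-region` pragmas,
#' so that [readGff3()] recovers the same genes.
#'
#' @param records a [GenomeRecord-class] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(records, path) {
  if (is(records, "GenomeRecord")) records <- list(records)
  out <- c("##gff-version 3")
  for (rec in records)
    out <- c(out, sprintf("##sequence-region %s 1 %d", rec@contigId,
                          rec@contigLength))
  for (rec in records) {
    gr <- rec@genes
    mc <- S4Vectors::mcols(gr)
    for (i in seq_along(gr)) {
      attrs <- c(paste0("ID=", .gffEscape(mc$gene_id[i])))
      if (nzchar(mc$product[i]))
        attrs <- c(attrs, paste0("product=", .gffEscape(mc$product[i])))
      for (ns in .namespaceColumns(gr)) {
        labs <- mc[[ns]][[i]]
        if (length(labs)) {
          key <- names(.ATTR_NAMESPACES)[.ATTR_NAMESPACES == ns]
          if (!length(key)) key <- tolower(ns)
          attrs <- c(attrs, paste0(key, "=",
                                   paste(.gffEscape(labs), collapse = ",")))
        }
      }
      out <- c(out, paste(rec@contigId, "GeneNeighborhoods", "CDS",
                          GenomicRanges::start(gr)[i],
                          GenomicRanges::end(gr)[i], ".",
                          as.character(GenomicRanges::strand(gr))[i], "0",
                          paste(attrs, collapse = ";"), sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}
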