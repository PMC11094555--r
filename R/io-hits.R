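.OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular homology hit list
#'
#' Parses 12-column tab-separated alignment output (the BLAST/DIAMOND
#' "outfmt 6" layout: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore), optionally extended with `qcovhsp`
#' and `scovhsp` columns (13-14) and a GTDB-style subject taxonomy string
#' (15). When the coverage columns are absent both coverages are recorded
#' as 100 — i.e. non-restrictive — with a warning.
#'
#' @param path tab-separated file without header.
#' @return hit data.frame (see [hit-tables]), one row per input row.
#' @seealso [filterHits()], [writeHits()]
#' @export
readHits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), q_cov = numeric(0),
                      s_cov = numeric(0), subject_taxonomy = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!nf %in% c(12L, 14L, 15L))
  if (length(bad))
    stop("row ", bad[1], ": expected 12, 14 or 15 tab-separated columns, ",
         "found ", nf[bad[1]])
  if (length(unique(nf)) > 1L)
    stop("inconsistent column counts across rows")
  ncols <- nf[1]
  m <- do.call(rbind, fields)
  num <- function(j) as.numeric(m[, j])
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3), evalue = num(11), bitscore = num(12),
    q_cov = if (ncols >= 14L) num(13) else rep(100, nrow(m)),
    s_cov = if (ncols >= 14L) num(14) else rep(100, nrow(m)),
    subject_taxonomy = if (ncols >= 15L) m[, 15] else rep("", nrow(m)),
    stringsAsFactors = FALSE)
  if (ncols == 12L)
    warning("no qcovhsp/scovhsp columns; recording both coverages as 100")
  badNum <- which(is.na(hits$evalue) | is.na(hits$bitscore) |
                  is.na(hits$pct_identity))
  if (length(badNum))
    stop("row ", badNum[1], ": unparseable numeric field")
  hits
}

#' Write a hit table as extended tabular output
#'
#' Emits 15 tab-separated columns: the 12 standard ones (alignment
#' book-keeping columns that the hit table does not carry are written as
#' 0), then `qcovhsp`, `scovhsp` and the subject taxonomy string, so that
#' [readHits()] round-trips the [hit-tables] fields.
#'
#' @param hits hit data.frame (see [hit-tables]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  .checkHitTable(hits)
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    paste(hits$query_id[i], hits$subject_id[i],
          format(hits$pct_identity[i], digits = 6),
          0, 0, 0, 0, 0, 0, 0,
          format(hits$evalue[i], digits = 6, scientific = TRUE),
          format(hits$bitscore[i], digits = 6),
          format(hits$q_cov[i], digits = 6),
          format(hits$s_cov[i], digits = 6),
          hits$subject_taxonomy[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
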