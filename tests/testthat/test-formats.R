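test_that("GFF3 reading recovers genes, labels and contig lengths", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region ctgA 1 9000",
    paste("ctgA", "src", "CDS", "100", "400", ".", "+", "0",
          "ID=gene1;product=widget synthase", sep = "\t"),
    paste("ctgA", "src", "CDS", "900", "1400", ".", "-", "0",
          "ID=gene2;pfam=PF18765,PF01934;Dbxref=KEGG:K00001", sep = "\t"),
    paste("ctgA", "src", "tRNA", "2000", "2100", ".", "+", ".",
          "ID=trna1", sep = "\t")), gff)
  recs <- suppressMessages(readGff3(gff))
  expect_length(recs, 1L)
  rec <- recs[[1]]
  expect_equal(rec@contigLength, 9000L)
  gr <- genes(rec)
  expect_length(gr, 2L)  # tRNA skipped
  mc <- S4Vectors::mcols(gr)
  expect_equal(mc$gene_id, c("gene1", "gene2"))
  expect_equal(GenomicRanges::start(gr), c(100L, 900L))
  expect_equal(mc$product[1], "widget synthase")
  # comma-separated pfam attribute becomes a 2-label set
  expect_setequal(as.character(mc$Pfam[[2]]), c("PF18765", "PF01934"))
  expect_equal(as.character(mc$KEGG[[2]]), "K00001")
})

test_that("GFF3 reader reports bad lines and missing sequence-region", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctgA\tsrc\tCDS\t100\t400\t.\t+\t0",  # 8 fields
               ""), bad)
  expect_error(suppressMessages(readGff3(bad)), "line 2")
  noreg <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("ctgA", "src", "CDS", "100", "400", ".", "+", "0",
                     "ID=g1", sep = "\t")), noreg)
  expect_warning(recs <- suppressMessages(readGff3(noreg)),
                 "inferring length")
  expect_equal(recs[[1]]@contigLength, 400L)
})

test_that("GenBank reading handles complement locations and LOCUS length", {
  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       ctgB              5000 bp    DNA     linear   BCT",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             100..400",
    "                     /locus_tag=\"b1\"",
    "                     /product=\"alpha subunit\"",
    "                     /db_xref=\"Pfam:PF00001\"",
    "     CDS             complement(900..1200)",
    "                     /locus_tag=\"b2\"",
    "                     /product=\"beta subunit\"",
    "                     /db_xref=\"KEGG:K00002\"",
    "                     /translation=\"MKV",
    "                     LLG\"",
    "ORIGIN",
    "//"), gbk)
  recs <- readGenBank(gbk)
  expect_length(recs, 1L)
  rec <- recs[[1]]
  expect_equal(rec@contigLength, 5000L)
  gr <- genes(rec)
  mc <- S4Vectors::mcols(gr)
  expect_equal(mc$gene_id, c("b1", "b2"))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  expect_equal(GenomicRanges::start(gr)[2], 900L)
  expect_equal(GenomicRanges::end(gr)[2], 1200L)
  expect_equal(as.character(mc$Pfam[[1]]), "PF00001")
  expect_equal(mc$protein_seq[2], "MKVLLG")
  # compound locations collapse to the outer span with a warning
  gbk2 <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       ctgC              4000 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(100..200,300..500)",
    "                     /locus_tag=\"c1\"",
    "//"), gbk2)
  expect_warning(r2 <- readGenBank(gbk2), "outer span")
  expect_equal(GenomicRanges::start(genes(r2[[1]])), 100L)
  expect_equal(GenomicRanges::end(genes(r2[[1]])), 500L)
  expect_error(readGenBank(tempfile()), "no such file")
})

test_that("GFF3 and GenBank writers agree on a dual-encoded fixture", {
  s <- generateNeighborhoodSet(fixtureSpec(nNeighborhoods = 3, seed = 21),
                               dir = (d <- tempfile()))
  files <- attr(s, "files")
  a <- suppressMessages(readGff3(files[["gff3"]]))
  b <- readGenBank(files[["genbank"]])
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    ga <- genes(a[[i]])
    gb <- genes(b[[i]])
    expect_equal(S4Vectors::mcols(ga)$gene_id, S4Vectors::mcols(gb)$gene_id)
    expect_equal(GenomicRanges::start(ga), GenomicRanges::start(gb))
    expect_equal(GenomicRanges::end(ga), GenomicRanges::end(gb))
    expect_equal(as.character(GenomicRanges::strand(ga)),
                 as.character(GenomicRanges::strand(gb)))
    expect_equal(as.list(S4Vectors::mcols(ga)$Pfam),
                 as.list(S4Vectors::mcols(gb)$Pfam))
    expect_equal(a[[i]]@contigLength, b[[i]]@contigLength)
  }
})

test_that("neighborhood CSV round-trips all dialect fields", {
  s <- generateNeighborhoodSet(fixtureSpec(
    nNeighborhoods = 3, noiseLabelPool = c("PF09000", "PF09001"), seed = 8))
  path <- tempfile(fileext = ".csv")
  writeNeighborhoodCsv(s, path)
  s2 <- readNeighborhoodCsv(path)
  expect_equal(neighborhoodIds(s2), neighborhoodIds(s))
  expect_equal(activeNamespace(s2), "Pfam")
  for (i in seq_along(s)) {
    n1 <- s[[i]]
    n2 <- s2[[i]]
    g1 <- genes(n1)
    g2 <- genes(n2)
    expect_equal(S4Vectors::mcols(g2)$gene_id, S4Vectors::mcols(g1)$gene_id)
    expect_equal(GenomicRanges::start(g2), GenomicRanges::start(g1))
    expect_equal(GenomicRanges::end(g2), GenomicRanges::end(g1))
    expect_equal(as.character(GenomicRanges::strand(g2)),
                 as.character(GenomicRanges::strand(g1)))
    expect_equal(S4Vectors::mcols(g2)$product, S4Vectors::mcols(g1)$product)
    expect_equal(as.list(S4Vectors::mcols(g2)$Pfam),
                 as.list(S4Vectors::mcols(g1)$Pfam))
    expect_equal(anchorId(n2), anchorId(n1))
    expect_equal(n2@genomeId, n1@genomeId)
    expect_equal(n2@contigId, n1@contigId)
    expect_equal(taxonomyOf(n2), taxonomyOf(n1))
  }
  # writing the re-read set reproduces the file byte for byte
  path2 <- tempfile(fileext = ".csv")
  writeNeighborhoodCsv(s2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("CSV validation errors name the problem", {
  s <- generateNeighborhoodSet(fixtureSpec(nNeighborhoods = 1, seed = 3))
  path <- tempfile(fileext = ".csv")
  writeNeighborhoodCsv(s, path)
  df <- utils::read.csv(path, colClasses = "character")
  # two anchor rows in one neighborhood
  df2 <- df
  df2$is_anchor[1:2] <- "1"
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, p2, row.names = FALSE)
  expect_error(readNeighborhoodCsv(p2), "exactly one anchor")
  # missing mandatory column
  df3 <- df[, setdiff(names(df), "strand")]
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(df3, p3, row.names = FALSE)
  expect_error(readNeighborhoodCsv(p3), "strand")
  # header-only file reads as an empty set
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(df[0, ], p4, row.names = FALSE)
  expect_length(readNeighborhoodCsv(p4), 0L)
})

test_that("hit tables parse 12-, 14- and 15-column layouts", {
  row12 <- paste("q1", "s1", "45.2", "200", "80", "3", "1", "200", "5",
                 "204", "3e-42", "180.5", sep = "\t")
  p <- tempfile()
  writeLines(row12, p)
  expect_warning(h <- readHits(p), "coverages as 100")
  expect_equal(h$evalue, 3e-42)
  expect_equal(h$bitscore, 180.5)
  expect_equal(h$q_cov, 100)
  row15 <- paste("q1", "s2", "88", "200", "8", "0", "1", "200", "1", "200",
                 "1e-80", "410", "80", "75",
                 "d__Archaea;g__Methanosarcina", sep = "\t")
  writeLines(row15, p)
  h2 <- readHits(p)
  expect_equal(h2$q_cov, 80)
  expect_equal(h2$s_cov, 75)
  expect_match(h2$subject_taxonomy, "Methanosarcina")
  writeLines("a\tb\tc", p)
  expect_error(readHits(p), "row 1")
  # round-trip through the writer
  hits <- generateHits(25, seed = 4)
  writeHits(hits, p)
  h3 <- readHits(p)
  expect_equal(h3$query_id, hits$query_id)
  expect_equal(h3$s_cov, hits$s_cov, tolerance = 1e-5)
  expect_equal(log10(h3$evalue), log10(hits$evalue), tolerance = 1e-5)
})

test_that("GTDB taxonomy strings parse and format round-trip", {
  tax <- parseTaxonomy("d__Archaea;g__Methanosarcina")
  expect_equal(tax$rank, c("domain", "genus"))
  expect_equal(tax$name, c("Archaea", "Methanosarcina"))
  expect_equal(nrow(parseTaxonomy("")), 0L)
  expect_error(parseTaxonomy("x__Foo"), "x__Foo")
  full <- "d__Bacteria;p__Bacillota;c__Bacilli;o__Bacillales;f__Bacillaceae;g__Bacillus;s__Bacillus subtilis"
  expect_equal(formatTaxonomy(parseTaxonomy(full)), full)
  # empty names are dropped by default
  expect_equal(parseTaxonomy("d__Archaea;p__;g__Methanosarcina")$rank,
               c("domain", "genus"))
})
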