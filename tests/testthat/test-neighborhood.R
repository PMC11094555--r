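test_that("window extraction keeps contained genes and drops edge-crossers", {
  gr <- geneRanges("ctg", c("g1", "g2", "g3"), c(100, 900, 5000),
                   c(400, 1200, 5300), c("+", "+", "-"))
  gn <- genomeRecord("ctg", gr, contigLength = 6000)

  n <- extractNeighborhood(gn, "g2", windowBp = 1000)
  expect_equal(unname(windowBounds(n)), c(1L, 2200L))
  expect_equal(S4Vectors::mcols(genes(n))$gene_id, c("g1", "g2"))
  expect_false(isFlipped(n))

  # a gene spanning the window edge at 2200 is excluded
  gr2 <- geneRanges("ctg", c("g1", "g2", "gx", "g3"),
                    c(100, 900, 2100, 5000), c(400, 1200, 2400, 5300),
                    c("+", "+", "+", "-"))
  n2 <- extractNeighborhood(genomeRecord("ctg", gr2, contigLength = 6000),
                            "g2", windowBp = 1000)
  expect_equal(S4Vectors::mcols(genes(n2))$gene_id, c("g1", "g2"))

  # single-gene genome: the anchor alone
  g1 <- genomeRecord("c", geneRanges("c", "g1", 100, 400, "+"),
                     contigLength = 1000)
  expect_equal(S4Vectors::mcols(genes(extractNeighborhood(g1, "g1")))$gene_id,
               "g1")

  # default window is +/- 10 kb per side
  expect_identical(formals(extractNeighborhood)$windowBp, 10000)
})

test_that("extraction errors name the offending anchor", {
  gn <- genomeRecord("c", geneRanges("c", "g1", 100, 400, "+"),
                     contigLength = 1000)
  expect_error(extractNeighborhood(gn, "missing"), "anchor not found: missing")
  dup <- GenomicRanges::GRanges("c", IRanges::IRanges(c(100, 600),
                                                      c(400, 900)),
                                strand = c("+", "+"))
  S4Vectors::mcols(dup) <- S4Vectors::DataFrame(gene_id = c("g1", "g1"),
                                                product = c("", ""))
  gn@genes <- dup  # bypass constructor checks to exercise the error path
  expect_error(extractNeighborhood(gn, "g1"), "duplicate gene id")
})

test_that("window rule holds on random genomes (brute-force check)", {
  for (seed in 1:25) {
    gn <- generateGenome(nGenes = 20, seed = seed)
    gr <- genes(gn)
    withr::with_seed(seed, {
      anchor <- sample(S4Vectors::mcols(gr)$gene_id, 1)
      w <- sample(c(500L, 2000L, 10000L), 1)
    })
    n <- extractNeighborhood(gn, anchor, windowBp = w)
    wb <- windowBounds(n)
    aIdx <- which(S4Vectors::mcols(gr)$gene_id == anchor)
    expect_equal(unname(wb["start"]),
                 max(1L, GenomicRanges::start(gr)[aIdx] - w))
    expect_equal(unname(wb["end"]),
                 min(gn@contigLength, GenomicRanges::end(gr)[aIdx] + w))
    # per-gene independent containment check
    expectIn <- S4Vectors::mcols(gr)$gene_id[
      GenomicRanges::start(gr) >= wb["start"] &
        GenomicRanges::end(gr) <= wb["end"]]
    got <- S4Vectors::mcols(genes(n))$gene_id
    expect_setequal(got, union(expectIn, anchor))
    expect_true(anchor %in% got)
    # ascending order
    expect_false(is.unsorted(GenomicRanges::start(genes(n))))
  }
})

test_that("flip reflects coordinates, toggles strands, and is an involution", {
  gr <- geneRanges("ctg", c("g1", "g2"), c(100, 900), c(400, 1200),
                   c("+", "+"))
  n <- neighborhood("n1", "g2", gr, windowStart = 1L, windowEnd = 2200L)
  f <- flipNeighborhood(n)
  # gene (900-1200, +) reflects to (1001-1301, -) in window [1, 2200]
  fg <- genes(f)
  i <- which(S4Vectors::mcols(fg)$gene_id == "g2")
  expect_equal(GenomicRanges::start(fg)[i], 1001)
  expect_equal(GenomicRanges::end(fg)[i], 1301)
  expect_equal(as.character(GenomicRanges::strand(fg))[i], "-")
  expect_true(isFlipped(f))
  # involution: flip twice restores everything
  ff <- flipNeighborhood(f)
  expect_equal(GenomicRanges::start(genes(ff)), GenomicRanges::start(gr))
  expect_equal(as.character(GenomicRanges::strand(genes(ff))),
               as.character(GenomicRanges::strand(gr)))
  expect_false(isFlipped(ff))
  # flip reverses the gene order exactly
  expect_equal(S4Vectors::mcols(genes(f))$gene_id,
               rev(S4Vectors::mcols(genes(n))$gene_id))
})

test_that("orientation normalization puts every anchor on plus and is idempotent", {
  plus <- nbhFromLabels(list("A", "B"), id = "p", anchorIndex = 1L)
  minus <- nbhFromLabels(list("A", "B"), id = "m", anchorIndex = 2L,
                         strands = c("+", "-"))
  s <- neighborhoodSet(list(plus, minus), activeNamespace = "Pfam")
  norm <- normalizeOrientation(s)
  anchStr <- vapply(as.list(norm), function(n)
    as.character(GenomicRanges::strand(anchorGene(n))), character(1))
  expect_true(all(anchStr == "+"))
  expect_equal(neighborhoodIds(norm), c("p", "m"))
  # untouched neighborhood is returned unchanged
  expect_identical(norm[[1]], plus)
  # idempotent
  norm2 <- normalizeOrientation(norm)
  expect_equal(vapply(as.list(norm2), isFlipped, logical(1)),
               vapply(as.list(norm), isFlipped, logical(1)))
})

test_that("term search is case-insensitive over products and all namespaces", {
  prods <- c("flagellar M-ring protein FliF",
             "flagellar motor switch protein FliG",
             "hypothetical protein")
  gr <- geneRanges("c", c("g1", "g2", "g3"), c(1, 500, 1000),
                   c(300, 800, 1300), rep("+", 3), product = prods,
                   labels = list(Pfam = list(character(0), character(0),
                                             "PF18765")))
  n <- neighborhood("n1", "g1", gr, windowStart = 1L, windowEnd = 2000L)
  s <- neighborhoodSet(list(n), activeNamespace = "Pfam")
  expect_equal(searchTerm(s, "flagellar")$gene_id, c("g1", "g2"))
  expect_equal(searchTerm(s, "pf18765")$gene_id, "g3")  # label, lower case
  expect_equal(nrow(searchTerm(s, "")), 0L)             # empty term: nothing
  expect_equal(nrow(searchTerm(s, "absent-term")), 0L)
})
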