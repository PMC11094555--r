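test_that("color assignment follows the more-than-twice rule", {
  # label A occurs 3 times, B twice: only A gets a color
  n1 <- nbhFromLabels(list("A", "B"), id = "n1")
  n2 <- nbhFromLabels(list("A", "B"), id = "n2")
  n3 <- nbhFromLabels(list("A", "C"), id = "n3")
  s <- neighborhoodSet(list(n1, n2, n3), activeNamespace = "Pfam")
  cm <- assignColors(s)
  expect_equal(names(cm$assignments), "A")
  expect_equal(cm$counts[["A"]], 3L)
  expect_equal(cm$counts[["B"]], 2L)
  # threshold is tunable
  cm2 <- assignColors(s, renderOptions(highlightMinCount = 2))
  expect_setequal(names(cm2$assignments), c("A", "B"))
  # no labels anywhere -> no assignments
  bare <- neighborhoodSet(list(nbhFromLabels(list(character(0)))),
                          activeNamespace = "Pfam")
  expect_length(assignColors(bare)$assignments, 0L)
})

test_that("equal counts take palette slots in lexicographic order", {
  mk <- function(id, labs) nbhFromLabels(labs, id = id)
  s <- neighborhoodSet(list(
    mk("x1", list("B", "A")), mk("x2", list("B", "A")),
    mk("x3", list("B", "A")), mk("x4", list("B", "A"))),
    activeNamespace = "Pfam")
  cm <- assignColors(s)
  expect_equal(names(cm$assignments), c("A", "B"))
  opts <- renderOptions()
  expect_equal(unname(cm$assignments), opts$palette[1:2])
  # a gene with two labels increments both counts once each
  expect_equal(cm$counts[["A"]], 4L)
})

test_that("SVG output parses, counts glyphs, and is byte-identical", {
  skip_if_not_installed("xml2")
  s <- generateNeighborhoodSet(fixtureSpec(nNeighborhoods = 2,
                                           genesPerNeighborhood = c(5, 5),
                                           seed = 13))
  svg1 <- renderSvg(s)
  svg2 <- renderSvg(s)
  expect_identical(svg1, svg2)  # no timestamps, no randomness
  doc <- xml2::read_xml(svg1)
  glyphs <- xml2::xml_find_all(
    doc, "//*[local-name()='polygon'][@class='gene']")
  totalGenes <- sum(vapply(as.list(s), function(n) length(genes(n)),
                           integer(1)))
  expect_length(glyphs, totalGenes)
  # machine-readable attributes present on every glyph
  expect_true(all(nzchar(xml2::xml_attr(glyphs, "data-gene-id"))))
  expect_true(all(nzchar(xml2::xml_attr(glyphs, "data-neighborhood-id"))))
  # empty set still renders a valid document with zero glyphs
  empty <- renderSvg(neighborhoodSet(activeNamespace = "Pfam"))
  expect_length(xml2::xml_find_all(xml2::read_xml(empty),
                                   "//*[local-name()='polygon']"), 0L)
})

test_that("glyph geometry respects scale and anchor centering", {
  skip_if_not_installed("xml2")
  s <- generateNeighborhoodSet(fixtureSpec(nNeighborhoods = 3, seed = 17))
  opts <- renderOptions(pxPerKb = 40)
  doc <- xml2::read_xml(renderSvg(s, options = opts))
  glyphs <- xml2::xml_find_all(
    doc, "//*[local-name()='polygon'][@class='gene']")
  coords <- lapply(glyphs, function(g) {
    pts <- strsplit(strsplit(xml2::xml_attr(g, "points"), " ")[[1]], ",")
    xs <- vapply(pts, function(p) as.numeric(p[1]), numeric(1))
    ys <- vapply(pts, function(p) as.numeric(p[2]), numeric(1))
    list(x = xs, y = ys)
  })
  ids <- xml2::xml_attr(glyphs, "data-gene-id")
  geneLen <- unlist(lapply(as.list(s), function(n) {
    stats::setNames(GenomicRanges::end(genes(n)) -
                      GenomicRanges::start(genes(n)) + 1,
                    S4Vectors::mcols(genes(n))$gene_id)
  }))
  for (k in seq_along(glyphs)) {
    extent <- max(coords[[k]]$x) - min(coords[[k]]$x)
    expect_lt(abs(extent - geneLen[[ids[k]]] * opts$pxPerKb / 1000), 0.5)
  }
  # anchor midpoints share one x within 0.5 px
  anchorIds <- vapply(as.list(s), anchorId, character(1))
  mids <- vapply(which(ids %in% anchorIds), function(k)
    (max(coords[[k]]$x) + min(coords[[k]]$x)) / 2, numeric(1))
  expect_lt(max(mids) - min(mids), 0.5)
})

test_that("the track cap is enforced", {
  nbhs <- lapply(seq_len(11), function(i)
    nbhFromLabels(list("A"), id = paste0("t", i)))
  s <- neighborhoodSet(nbhs, activeNamespace = "Pfam")
  expect_error(renderSvg(s, options = renderOptions(maxTracks = 10)),
               "track limit exceeded \\(10\\)")
  expect_equal(formals(renderOptions)$maxTracks, 500)
  expect_silent(renderSvg(s))  # 11 <= default 500
})

test_that("palette recycles with a warning when exhausted", {
  nbhs <- lapply(1:3, function(i)
    nbhFromLabels(as.list(sprintf("L%02d", 1:25)), id = paste0("p", i)))
  s <- neighborhoodSet(nbhs, activeNamespace = "Pfam")
  expect_warning(cm <- assignColors(s), "recycling")
  expect_length(cm$assignments, 25L)
  expect_equal(unname(cm$assignments[21]), unname(cm$assignments[1]))
})
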