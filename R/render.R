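## fixed 20-color qualitative palette (deterministic figures); recycled
## with a warning when more labels qualify than there are colors
.PALETTE20 <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
  "#8c564b", "#e377c2", "#bcbd22", "#17becf", "#aec7e8",
  "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5", "#c49c94",
  "#f7b6d2", "#dbdb8d", "#9edae5", "#393b79", "#ad494a")

#' Rendering options
#'
#' @param pxPerKb horizontal scale in pixels per kilobase (default 40).
#' @param trackHeight track height in pixels (default 22).
#' @param highlightMinCount minimum number of occurrences (across the
#'   whole set, per gene per distinct label) for a label to receive a
#'   color; the default 3 encodes the "highlight annotations occurring
#'   more than twice" rule.
#' @param defaultColor fill for unhighlighted genes (default gray).
#' @param palette ordered vector of hex colors (default: a fixed 20-color
#'   qualitative palette).
#' @param showTaxonomy draw a taxonomy label left of each track?
#' @param centerOnAnchor translate tracks so all anchor midpoints share one
#'   x-coordinate (default `TRUE`)?
#' @param maxTracks maximum number of neighborhoods drawable in one figure
#'   (default 500).
#' @return a validated list of class `"RenderOptions"`.
#' @seealso [assignColors()], [renderSvg()]
#' @export
renderOptions <- function(pxPerKb = 40, trackHeight = 22,
                          highlightMinCount = 3,
                          defaultColor = "#c8c8c8",
                          palette = .PALETTE20,
                          showTaxonomy = TRUE,
                          centerOnAnchor = TRUE,
                          maxTracks = 500) {
  stopifnot(pxPerKb > 0, trackHeight > 0, highlightMinCount >= 1,
            length(palette) >= 1, maxTracks >= 1)
  structure(list(pxPerKb = pxPerKb, trackHeight = trackHeight,
                 highlightMinCount = highlightMinCount,
                 defaultColor = defaultColor, palette = palette,
                 showTaxonomy = showTaxonomy,
                 centerOnAnchor = centerOnAnchor,
                 maxTracks = as.integer(maxTracks)),
            class = "RenderOptions")
}

#' Assign colors to frequently occurring annotation labels
#'
#' Counts every label of the active namespace across the whole set (a gene
#' contributes one count per distinct label it carries) and gives palette
#' colors to labels reaching `highlightMinCount` occurrences — by default
#' those occurring more than twice. Colors are assigned in descending-count
#' order with lexicographic tie-breaking, so the mapping is stable across
#' runs; when more labels qualify than the palette holds, colors recycle
#' with a warning. Genes carrying no colored label render in
#' `defaultColor`.
#'
#' @param s a [NeighborhoodSet-class].
#' @param options a [renderOptions()] object.
#' @return list of class `"ColorMap"` with components `assignments` (named
#'   character vector label -> hex color) and `counts` (named integer
#'   vector of label occurrence counts).
#' @export
assignColors <- function(s, options = renderOptions()) {
  stopifnot(is(s, "NeighborhoodSet"))
  ns <- activeNamespace(s)
  all <- unlist(lapply(s, function(n) {
    unlist(lapply(as.list(geneLabels(n, ns)), unique), use.names = FALSE)
  }), use.names = FALSE)
  counts <- if (length(all)) table(all) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  eligible <- counts[counts >= options$highlightMinCount]
  if (length(eligible))
    eligible <- eligible[order(-eligible, names(eligible))]
  if (length(eligible) > length(options$palette))
    warning("palette exhausted (", length(eligible), " labels, ",
            length(options$palette), " colors); recycling colors")
  assignments <- if (length(eligible))
    stats::setNames(rep(options$palette,
                        length.out = length(eligible)), names(eligible))
  else stats::setNames(character(0), character(0))
  structure(list(assignments = assignments, counts = counts),
            class = "ColorMap")
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.px <- function(x) formatC(x, format = "f", digits = 2)

## arrow polygon points for one gene glyph
.genePoints <- function(x1, x2, y0, y1, strand) {
  w <- x2 - x1
  h <- min(w, 8)
  ym <- (y0 + y1) / 2
  pts <- if (strand == "+")
    list(c(x1, y0), c(x2 - h, y0), c(x2, ym), c(x2 - h, y1), c(x1, y1))
  else
    list(c(x1 + h, y0), c(x2, y0), c(x2, y1), c(x1 + h, y1), c(x1, ym))
  paste(vapply(pts, function(p) paste0(.px(p[1]), ",", .px(p[2])),
               character(1)), collapse = " ")
}

#' Render a NeighborhoodSet as a multi-track SVG figure
#'
#' Draws one horizontal track per neighborhood (in the order of `ordering`
#' when given, else input order). Genes are directional arrow polygons —
#' the point follows the strand — at `pxPerKb` pixels per kilobase, filled
#' by [assignColors()]. With `centerOnAnchor` every track is translated so
#' the anchor midpoints share a common x-coordinate. A taxonomy label at
#' the set's display rank (falling back to the genome id) sits left of
#' each track, and a legend lists every colored label. Every gene element
#' carries `data-gene-id`, `data-neighborhood-id` and `data-labels`
#' attributes and class `gene`, so glyphs are countable by XML parsing.
#' The output contains no timestamps or randomness and is byte-identical
#' across runs.
#'
#' @param s a [NeighborhoodSet-class] with at most `maxTracks`
#'   neighborhoods.
#' @param ordering optional [ClusterOrdering-class] (or integer
#'   permutation) giving the track order.
#' @param options a [renderOptions()] object.
#' @return the SVG document as a single character string.
#' @examples
#' ## a set of 2 neighborhoods x 3 genes yields an SVG with exactly 6
#' ## elements of class "gene"
#' @export
renderSvg <- function(s, ordering = NULL, options = renderOptions()) {
  stopifnot(is(s, "NeighborhoodSet"))
  if (length(s) > options$maxTracks)
    stop(.trackLimitCondition(options$maxTracks))
  ord <- if (is.null(ordering)) seq_along(s)
         else if (is(ordering, "ClusterOrdering")) ordering@order
         else as.integer(ordering)
  cmap <- assignColors(s, options)
  ns <- activeNamespace(s)
  scale <- options$pxPerKb / 1000
  marginLeft <- if (options$showTaxonomy) 180 else 10
  marginTop <- 10
  pitch <- options$trackHeight + 8
  nbhs <- as.list(s)[ord]
  anchorMidBp <- vapply(nbhs, function(n) {
    a <- anchorGene(n)
    (GenomicRanges::start(a) + GenomicRanges::end(a)) / 2
  }, numeric(1))
  wStart <- vapply(nbhs, function(n) n@windowStart, integer(1))
  wEnd <- vapply(nbhs, function(n) n@windowEnd, integer(1))
  # per-track x offset in px: bp -> (bp - windowStart)*scale + offset
  offsets <- if (length(nbhs) == 0) numeric(0)
  else if (options$centerOnAnchor) {
    commonX <- marginLeft + max((anchorMidBp - wStart) * scale)
    commonX - (anchorMidBp - wStart) * scale
  } else rep(marginLeft, length(nbhs))
  widths <- (wEnd - wStart + 1) * scale + offsets
  legendRows <- length(cmap$assignments)
  height <- marginTop + length(nbhs) * pitch + 20 +
    legendRows * 16 + 20
  width <- max(c(widths, 300)) + 20
  out <- c(sprintf(paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
    "width=\"%s\" height=\"%s\" data-active-namespace=\"%s\">"),
    .px(width), .px(height), .xmlEscape(ns)))
  for (t in seq_along(nbhs)) {
    n <- nbhs[[t]]
    y0 <- marginTop + (t - 1) * pitch + 2
    y1 <- y0 + options$trackHeight - 4
    out <- c(out, sprintf(
      "<g class=\"track\" data-neighborhood-id=\"%s\">",
      .xmlEscape(n@neighborhoodId)))
    if (options$showTaxonomy) {
      lab <- .taxonomyName(n@taxonomy, taxonomyRank(s))
      if (!nzchar(lab)) lab <- n@genomeId
      out <- c(out, sprintf(paste0(
        "<text class=\"taxonomy-label\" x=\"4\" y=\"%s\" ",
        "font-size=\"11\" font-family=\"sans-serif\">%s</text>"),
        .px((y0 + y1) / 2 + 4), .xmlEscape(lab)))
    }
    out <- c(out, sprintf(
      "<line class=\"baseline\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#999999\" stroke-width=\"1\"/>",
      .px(offsets[t]), .px((y0 + y1) / 2),
      .px(offsets[t] + (wEnd[t] - wStart[t] + 1) * scale),
      .px((y0 + y1) / 2)))
    gr <- n@genes
    mc <- S4Vectors::mcols(gr)
    labs <- as.list(geneLabels(n, ns))
    for (i in seq_along(gr)) {
      x1 <- offsets[t] + (GenomicRanges::start(gr)[i] - wStart[t]) * scale
      x2 <- x1 + (GenomicRanges::end(gr)[i] -
                    GenomicRanges::start(gr)[i] + 1) * scale
      gl <- labs[[i]]
      colored <- gl[gl %in% names(cmap$assignments)]
      fill <- if (length(colored)) cmap$assignments[[colored[1]]] else
        options$defaultColor
      out <- c(out, sprintf(paste0(
        "<polygon class=\"gene\" data-gene-id=\"%s\" ",
        "data-neighborhood-id=\"%s\" data-labels=\"%s\" points=\"%s\" ",
        "fill=\"%s\" stroke=\"#333333\" stroke-width=\"0.5\"><title>%s",
        "</title></polygon>"),
        .xmlEscape(mc$gene_id[i]), .xmlEscape(n@neighborhoodId),
        .xmlEscape(paste(gl, collapse = ";")),
        .genePoints(x1, x2, y0, y1,
                    as.character(GenomicRanges::strand(gr))[i]),
        fill, .xmlEscape(mc$product[i])))
    }
    out <- c(out, "</g>")
  }
  # legend
  ly <- marginTop + length(nbhs) * pitch + 20
  out <- c(out, "<g class=\"legend\">")
  if (legendRows) {
    for (k in seq_along(cmap$assignments)) {
      y <- ly + (k - 1) * 16
      lab <- names(cmap$assignments)[k]
      out <- c(out, sprintf(paste0(
        "<rect class=\"legend-swatch\" data-label=\"%s\" x=\"10\" ",
        "y=\"%s\" width=\"12\" height=\"12\" fill=\"%s\"/>"),
        .xmlEscape(lab), .px(y), cmap$assignments[k]),
        sprintf(paste0(
          "<text class=\"legend-label\" x=\"26\" y=\"%s\" ",
          "font-size=\"11\" font-family=\"sans-serif\">%s (%d)</text>"),
          .px(y + 10), .xmlEscape(lab), cmap$counts[[lab]]))
    }
  }
  out <- c(out, "</g>", "</svg>")
  paste(out, collapse = "\n")
}
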