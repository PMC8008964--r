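# Glyph layout and figure rendering (deterministic SVG; raster PNG).

#' Rendering configuration
#'
#' Builds a validated \code{\link{RenderConfig}}.
#'
#' @param width,height canvas size in pixels.
#' @param rMin,rMax glyph radius bounds in embedding units; \code{NA} derives
#'   them from the embedding extent (\code{rMax} = 1.5\% of the larger
#'   extent, \code{rMin = rMax/4}).
#' @param clipQuantile quantile in (0, 1] for intensity/total clipping.
#' @param lightenColors interpolate slice colors toward white as intensity
#'   falls (default \code{TRUE}).
#' @param emptyColor hex color of the neutral dot for zero-expression cells.
#' @param format \code{"svg"} (reference output) or \code{"png"}.
#' @param dpi raster resolution for PNG.
#' @param legendFraction fraction of the canvas width reserved for the
#'   legend margin.
#' @return a \code{RenderConfig}.
#' @export
renderConfig <- function(width = 900, height = 700, rMin = NA_real_,
                         rMax = NA_real_, clipQuantile = 0.99,
                         lightenColors = TRUE, emptyColor = "#BFBFBF",
                         format = c("svg", "png"), dpi = 150,
                         legendFraction = 0.2) {
  format <- match.arg(format)
  methods::new("RenderConfig", width = as.numeric(width),
               height = as.numeric(height), rMin = as.numeric(rMin),
               rMax = as.numeric(rMax), clipQuantile = clipQuantile,
               lightenColors = lightenColors, emptyColor = emptyColor,
               format = format, dpi = as.numeric(dpi),
               legendFraction = legendFraction)
}

#' Lay out one pie glyph
#'
#' Turns a cell's slice fractions and fill colors into wedge geometry.
#' Wedges start at 12 o'clock and proceed clockwise in gene-list order; the
#' arc of wedge \eqn{i} is \eqn{360 \cdot fraction_i} degrees. Zero-fraction
#' genes produce no wedge. An empty cell produces a glyph with no wedges
#' (drawn as a neutral dot).
#'
#' @param cellId cell identifier.
#' @param center numeric length-2 glyph center (embedding units).
#' @param radius glyph radius (> 0, embedding units).
#' @param fracs named vector of slice fractions (non-negative, summing to 1
#'   for a non-empty cell, or all zero).
#' @param fills character vector of hex fill colors, one per fraction.
#' @return a \code{\link{PieGlyph}}.
#' @export
#' @examples
#' g <- layoutGlyph("c1", c(0, 0), 1, c(A = 0.25, B = 0.75), c("#FF0000", "#0000FF"))
#' wedges(g)  # 0-90 and 90-360 degrees
layoutGlyph <- function(cellId, center, radius, fracs, fills) {
  isEmpty <- !any(fracs > 0)
  keep <- fracs > 0
  if (isEmpty) {
    w <- data.frame(gene = character(), start = numeric(), end = numeric(),
                    fill = character(), stringsAsFactors = FALSE)
  } else {
    arcs <- 360 * fracs[keep]
    ends <- cumsum(arcs)
    w <- data.frame(gene = names(fracs)[keep],
                    start = c(0, head(ends, -1)), end = ends,
                    fill = fills[keep], stringsAsFactors = FALSE)
  }
  methods::new("PieGlyph", cellId = as.character(cellId),
               center = as.numeric(center), radius = as.numeric(radius),
               wedges = w, isEmpty = isEmpty)
}

#' Lay out glyphs for a whole composition set
#'
#' Applies \code{\link{layoutGlyph}} to every cell of a
#' \code{\link{CellCompositionSet}}: fills are the genes' base colors,
#' lightened toward white by each cell's per-gene intensity when
#' \code{lightenColors} is enabled.
#'
#' @param comp a \code{CellCompositionSet}.
#' @param assignment a \code{\link{ColorAssignment}} covering the
#'   composition's genes.
#' @param config a \code{\link{RenderConfig}}.
#' @return a list of \code{\link{PieGlyph}}, in composition (embedding) order.
#' @export
layoutGlyphs <- function(comp, assignment, config = renderConfig()) {
  genes <- comp@genes
  cols <- baseColors(assignment)
  missing <- setdiff(genes, rownames(cols))
  if (length(missing))
    stopf("color assignment lacks gene(s): %s", paste(missing, collapse = ", "))
  base <- cols[genes, , drop = FALSE]
  lapply(seq_along(comp@cellIds), function(i) {
    fr <- setNames(comp@fractions[i, ], genes)
    fills <- hexFromRgb(applyIntensity(base, comp@intensities[i, ],
                                       config@lightenColors))
    layoutGlyph(comp@cellIds[i], comp@coords[i, ], comp@radii[i], fr, fills)
  })
}

# data-space -> pixel-space transform preserving aspect ratio; SVG pixel
# y grows downward, embedding y grows upward
glyphTransform <- function(glyphs, config, legend = NULL) {
  ctr <- t(vapply(glyphs, function(g) g@center, numeric(2)))
  rad <- vapply(glyphs, function(g) g@radius, numeric(1))
  xr <- range(ctr[, 1] - rad, ctr[, 1] + rad)
  yr <- range(ctr[, 2] - rad, ctr[, 2] + rad)
  plotW <- config@width * (1 - if (!is.null(legend) && nrow(legend))
    config@legendFraction else 0)
  plotH <- config@height
  pad <- 0.04 * min(plotW, plotH)
  span <- function(r) max(diff(r), 1e-12)
  s <- min((plotW - 2 * pad) / span(xr), (plotH - 2 * pad) / span(yr))
  offx <- (plotW - s * span(xr)) / 2
  offy <- (plotH - s * span(yr)) / 2
  list(
    x = function(v) offx + (v - xr[1]) * s,
    yDown = function(v) plotH - (offy + (v - yr[1]) * s),
    yUp = function(v) offy + (v - yr[1]) * s,
    scale = s,
    legendX = plotW
  )
}

# arc endpoint at `deg` clockwise from 12 o'clock around (cx, cy);
# `ySign` +1 for y-up (plot) coordinates, -1 for y-down (SVG) coordinates
arcPoint <- function(cx, cy, r, deg, ySign) {
  th <- deg * pi / 180
  c(cx + r * sin(th), cy + ySign * r * cos(th))
}

fmt <- function(x) sprintf("%.3f", x)

svgWedge <- function(cx, cy, r, start, end, fill) {
  if (end - start >= 360 - 1e-9)
    return(sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                   fmt(cx), fmt(cy), fmt(r), fill))
  p1 <- arcPoint(cx, cy, r, start, ySign = -1)
  p2 <- arcPoint(cx, cy, r, end, ySign = -1)
  large <- as.integer((end - start) > 180)
  sprintf('<path d="M %s %s L %s %s A %s %s 0 %d 1 %s %s Z" fill="%s"/>',
          fmt(cx), fmt(cy), fmt(p1[1]), fmt(p1[2]), fmt(r), fmt(r), large,
          fmt(p2[1]), fmt(p2[2]), fill)
}

legendLayout <- function(legend, config) {
  # columns of at most 40 entries in the reserved right margin
  n <- nrow(legend)
  perCol <- 40L
  ncol <- max(1L, ceiling(n / perCol))
  data.frame(col = (seq_len(n) - 1L) %/% perCol,
             row = (seq_len(n) - 1L) %% perCol)
}

renderSvg <- function(glyphs, legend, config, path) {
  tr <- glyphTransform(glyphs, config, legend)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            round(config@width), round(config@height),
            round(config@width), round(config@height)),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            round(config@width), round(config@height))
  )
  for (g in glyphs) {
    cx <- tr$x(g@center[1])
    cy <- tr$yDown(g@center[2])
    r <- g@radius * tr$scale
    if (g@isEmpty) {
      out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                            fmt(cx), fmt(cy), fmt(r), config@emptyColor))
    } else {
      for (k in seq_len(nrow(g@wedges)))
        out <- c(out, svgWedge(cx, cy, r, g@wedges$start[k], g@wedges$end[k],
                               g@wedges$fill[k]))
    }
  }
  if (!is.null(legend) && nrow(legend)) {
    lay <- legendLayout(legend, config)
    colW <- (config@width - tr$legendX - 10) / (max(lay$col) + 1)
    rowH <- 16
    for (i in seq_len(nrow(legend))) {
      x0 <- tr$legendX + 10 + lay$col[i] * colW
      y0 <- 20 + lay$row[i] * rowH
      if (legend$is_header[i]) {
        out <- c(out, sprintf('<text x="%s" y="%s" font-family="Helvetica, Arial, sans-serif" font-size="12" font-weight="bold">%s</text>',
                              fmt(x0), fmt(y0), xmlEscape(legend$label[i])))
      } else {
        out <- c(out,
                 sprintf('<rect x="%s" y="%s" width="10" height="10" fill="%s"/>',
                         fmt(x0), fmt(y0 - 9), legend$color[i]),
                 sprintf('<text x="%s" y="%s" font-family="Helvetica, Arial, sans-serif" font-size="11">%s</text>',
                         fmt(x0 + 14), fmt(y0), xmlEscape(legend$label[i])))
      }
    }
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

wedgePolygon <- function(cx, cy, r, start, end) {
  degs <- seq(start, end, length.out = max(2L, ceiling((end - start) / 2) + 1L))
  th <- degs * pi / 180
  xs <- cx + r * sin(th)
  ys <- cy + r * cos(th)
  if (end - start < 360 - 1e-9) {
    xs <- c(cx, xs, cx)
    ys <- c(cy, ys, cy)
  }
  list(x = xs, y = ys)
}

renderPng <- function(glyphs, legend, config, path) {
  tr <- glyphTransform(glyphs, config, legend)
  grDevices::png(path, width = round(config@width), height = round(config@height),
                 units = "px", res = config@dpi, pointsize = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, config@width), ylim = c(0, config@height),
                        asp = 1)
  for (g in glyphs) {
    cx <- tr$x(g@center[1])
    cy <- config@height - tr$yDown(g@center[2])
    r <- g@radius * tr$scale
    if (g@isEmpty) {
      pol <- wedgePolygon(cx, cy, r, 0, 360)
      graphics::polygon(pol$x, pol$y, col = config@emptyColor, border = NA)
    } else {
      for (k in seq_len(nrow(g@wedges))) {
        pol <- wedgePolygon(cx, cy, r, g@wedges$start[k], g@wedges$end[k])
        graphics::polygon(pol$x, pol$y, col = g@wedges$fill[k], border = NA)
      }
    }
  }
  if (!is.null(legend) && nrow(legend)) {
    lay <- legendLayout(legend, config)
    colW <- (config@width - tr$legendX - 10) / (max(lay$col) + 1)
    rowH <- 16
    for (i in seq_len(nrow(legend))) {
      x0 <- tr$legendX + 10 + lay$col[i] * colW
      y0 <- config@height - (20 + lay$row[i] * rowH)
      if (legend$is_header[i]) {
        graphics::text(x0, y0, legend$label[i], adj = c(0, 0), font = 2)
      } else {
        graphics::rect(x0, y0, x0 + 10, y0 + 10, col = legend$color[i],
                       border = NA)
        graphics::text(x0 + 14, y0, legend$label[i], adj = c(0, 0))
      }
    }
  }
  invisible(path)
}

#' Render a pie-glyph figure
#'
#' Writes the laid-out glyphs (and an optional legend in a reserved right
#' margin) to SVG or PNG. The data-space to pixel mapping preserves the
#' embedding's aspect ratio; glyphs are drawn in input order, so overdraw is
#' deterministic, and identical inputs produce byte-identical SVG.
#'
#' @param glyphs non-empty list of \code{\link{PieGlyph}} objects.
#' @param legend optional legend entries from
#'   \code{\link{buildLegendEntries}}.
#' @param config a \code{\link{RenderConfig}}; its \code{format} selects the
#'   output type unless \code{format} is given.
#' @param path output file path.
#' @param format override of the output format (\code{"svg"} or
#'   \code{"png"}).
#' @return \code{path}, invisibly.
#' @export
renderFigure <- function(glyphs, legend = NULL, config = renderConfig(), path,
                         format = config@format) {
  if (length(glyphs) == 0)
    stopf("at least one glyph is required")
  format <- match.arg(format, c("svg", "png"))
  if (format == "svg") renderSvg(glyphs, legend, config, path)
  else renderPng(glyphs, legend, config, path)
  invisible(path)
}
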