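test_that("layoutGlyph places wedges clockwise from 12 o'clock", {
  g <- layoutGlyph("c1", c(0, 0), 1, c(A = 0.25, B = 0.75),
                   c("#FF0000", "#0000FF"))
  w <- wedges(g)
  expect_equal(w$start, c(0, 90))
  expect_equal(w$end, c(90, 360))
  expect_equal(w$fill, c("#FF0000", "#0000FF"))

  # single gene with fraction 1: one full-circle wedge
  full <- layoutGlyph("c2", c(1, 1), 0.5, c(A = 1), "#00FF00")
  expect_equal(nrow(wedges(full)), 1L)
  expect_equal(wedges(full)$end - wedges(full)$start, 360)

  # zero-fraction genes produce no wedge
  sparse <- layoutGlyph("c3", c(0, 0), 1, c(A = 0.5, B = 0, C = 0.5),
                        c("#111111", "#222222", "#333333"))
  expect_equal(wedges(sparse)$gene, c("A", "C"))

  # empty cell: no wedges, flagged empty
  e <- layoutGlyph("c4", c(0, 0), 0.1, c(A = 0, B = 0), c("#111111", "#222222"))
  expect_true(isEmptyCell(e))
  expect_equal(nrow(wedges(e)), 0L)
})

test_that("wedge arcs tile the full circle for non-empty glyphs", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    fr <- rexp(n) + 1e-6
    fr <- fr / sum(fr)
    g <- layoutGlyph("c", runif(2), runif(1, 0.1, 2),
                     setNames(fr, paste0("G", 1:n)), rep("#000000", n))
    arcs <- wedges(g)$end - wedges(g)$start
    expect_lt(abs(sum(arcs) - 360), 1e-6)
    expect_true(all(arcs > 0))
  }
})

test_that("empty cells become small neutral dots with radius rMin/2", {
  m <- toyMatrix(); m[, "c2"] <- 0
  sce <- alignCells(makeSCE(m), toyCoords())
  spec <- GeneListSpec(list(g1 = "G1", g2 = "G2"), c("blue", "red"))
  comp <- buildCellCompositions(sce, spec, rMin = 0.2, rMax = 0.8)
  glyphs <- layoutGlyphs(comp, assignColors(spec))
  expect_true(isEmptyCell(glyphs[[2]]))
  expect_equal(glyphRadii(glyphs[[2]]), 0.1)
  svg <- tempfile(fileext = ".svg")
  renderFigure(glyphs, NULL, renderConfig(), svg)
  # the gray dot is drawn with the configured empty-cell color
  expect_true(any(grepl("#BFBFBF", readLines(svg), fixed = TRUE)))
})

test_that("SVG output has the expected element count and is byte-deterministic", {
  g1 <- layoutGlyph("c1", c(0, 0), 1, c(A = 0.25, B = 0.75),
                    c("#FF0000", "#0000FF"))
  g2 <- layoutGlyph("c2", c(3, 1), 1, c(A = 1), "#00FF00")
  cfg <- renderConfig(width = 400, height = 300)

  f1 <- tempfile(fileext = ".svg")
  renderFigure(list(g1, g2), NULL, cfg, f1)
  doc <- readLines(f1)
  # two wedge paths for g1; the full-circle g2 renders as a circle
  expect_equal(sum(grepl("^<path ", doc)), 2L)
  expect_equal(sum(grepl("^<circle ", doc)), 1L)

  f2 <- tempfile(fileext = ".svg")
  renderFigure(list(g1, g2), NULL, cfg, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # parses as well-formed XML
  expect_silent(xml2::read_xml(f1))

  expect_error(renderFigure(list(), NULL, cfg, tempfile()), "at least one")
})

test_that("permuting input cells changes overdraw order but not geometry", {
  fix <- simulateCells(nClusters = 2, cellsPerCluster = 10, seed = 9)
  comp <- buildCellCompositions(fix$sce, fix$spec)
  asg <- assignColors(fix$spec)
  glyphs <- layoutGlyphs(comp, asg)

  perm <- rev(seq_len(ncol(fix$sce)))
  sceP <- fix$sce[, perm]
  xy <- SingleCellExperiment::reducedDim(fix$sce, "embedding")
  rownames(xy) <- colnames(fix$sce)
  sceP <- alignCells(sceP, xy[perm, ])
  compP <- buildCellCompositions(sceP, fix$spec)
  glyphsP <- layoutGlyphs(compP, asg)

  byId <- function(gl) setNames(gl, vapply(gl, function(g) g@cellId, ""))
  a <- byId(glyphs); b <- byId(glyphsP)
  for (id in names(a)) {
    expect_equal(a[[id]]@center, b[[id]]@center)
    expect_equal(a[[id]]@radius, b[[id]]@radius)
    expect_equal(a[[id]]@wedges$start, b[[id]]@wedges$start)
    expect_equal(a[[id]]@wedges$end, b[[id]]@wedges$end)
  }
})

test_that("a 500-cell figure renders to PNG and SVG with a legend", {
  fix <- simulateCells(nClusters = 5, cellsPerCluster = 100,
                       genesPerProgram = 3, seed = 13)
  comp <- buildCellCompositions(fix$sce, fix$spec)
  asg <- assignColors(fix$spec)
  leg <- buildLegendEntries(asg, fix$spec)
  glyphs <- layoutGlyphs(comp, asg)
  expect_length(glyphs, 500L)

  png <- tempfile(fileext = ".png")
  renderFigure(glyphs, leg, renderConfig(format = "png"), png)
  expect_gt(file.size(png), 0)

  svg <- tempfile(fileext = ".svg")
  renderFigure(glyphs, leg, renderConfig(), svg)
  doc <- readLines(svg)
  # every legend entry appears as text
  for (lbl in leg$label)
    expect_true(any(grepl(paste0(">", lbl, "<"), doc, fixed = TRUE)))
})
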