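test_that("delimited expression matrices round-trip in both orientations", {
  m <- toyMatrix()

  f1 <- writeToyCsv(m, tempfile(fileext = ".csv"))
  sce <- readExpressionMatrix(f1, orientation = "genes_as_rows")
  expect_equal(dim(sce), c(2L, 3L))
  expect_equal(as.matrix(SummarizedExperiment::assay(sce)), m)

  f2 <- writeToyCsv(m, tempfile(fileext = ".csv"), cellsAsRows = TRUE)
  sce2 <- readExpressionMatrix(f2, orientation = "cells_as_rows")
  expect_equal(as.matrix(SummarizedExperiment::assay(sce2)), m)

  # tab dialect auto-detected from extension
  f3 <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE), f3,
              sep = "\t", quote = FALSE, row.names = FALSE)
  sce3 <- readExpressionMatrix(f3)
  expect_equal(as.matrix(SummarizedExperiment::assay(sce3)), m)
})

test_that("MatrixMarket triples read back identical to the delimited form", {
  m <- toyMatrix()
  dir <- tempfile()
  dir.create(dir)
  mtx <- file.path(dir, "matrix.mtx")
  writeExpressionMatrix(m, mtx, format = "matrixmarket")
  sce <- readExpressionMatrix(mtx)
  expect_equal(unname(as.matrix(SummarizedExperiment::assay(sce))), unname(m))
  expect_equal(rownames(sce), rownames(m))
  expect_equal(colnames(sce), colnames(m))
})

test_that("invalid expression input is rejected", {
  m <- toyMatrix()
  m["G1", "c2"] <- -1
  f <- writeToyCsv(m, tempfile(fileext = ".csv"))
  expect_error(readExpressionMatrix(f), "negative")

  m2 <- toyMatrix()
  rownames(m2) <- c("G1", "G1")
  f2 <- writeToyCsv(m2, tempfile(fileext = ".csv"))
  expect_error(readExpressionMatrix(f2), "duplicate")

  expect_error(readExpressionMatrix(tempfile(fileext = ".csv")), "not found")
})

test_that("coordinate files are read in order and validated", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,x,y", "c1,0.0,0.0", "c2,1.0,1.0"), f)
  xy <- readCoordinates(f)
  expect_equal(rownames(xy), c("c1", "c2"))
  expect_equal(unname(xy), cbind(c(0, 1), c(0, 1)))

  writeLines(c("cell_id,x,y", "c1,0.0,NaN"), f)
  expect_error(readCoordinates(f), "non-finite")

  writeLines(c("cell_id,x", "c1,0.0"), f)
  expect_error(readCoordinates(f), "y")
})

test_that("gene lists parse with comments, order, and disjointness checks", {
  p1 <- writeGeneList(c("# a comment", "GATA1", "", "KLF1"))
  p2 <- writeGeneList(c("SPI1"))
  spec <- readGeneLists(c(p1, p2), c("winter", "#FF0000"),
                        groupNames = c("erythroid", "myeloid"))
  expect_s4_class(spec, "GeneListSpec")
  expect_equal(unname(groupSizes(spec)), c(2L, 1L))
  expect_equal(groupGenes(spec)$erythroid, c("GATA1", "KLF1"))
  expect_equal(nTotalGenes(spec), 3L)

  # single gene: N_total = 1
  solo <- readGeneLists(p2, "blue")
  expect_equal(nTotalGenes(solo), 1L)

  p3 <- writeGeneList(c("GATA1", "TAL1"))
  expect_error(readGeneLists(c(p1, p3), c("blue", "red")), "GATA1")
  expect_error(readGeneLists(writeGeneList("# only a comment"), "blue"),
               "no genes")
  expect_error(readGeneLists(c(p1, p2), "blue"), "one color rule per")
})

test_that("alignCells restricts to common cells in embedding order and is idempotent", {
  m <- cbind(toyMatrix(), c4 = c(7, 7))  # matrix has an extra cell
  sce <- makeSCE(m)
  xy <- toyCoords()[c(3, 1, 2), ]       # embedding order differs from matrix

  expect_message(al <- alignCells(sce, xy), "dropped 1 expression cell")
  expect_equal(colnames(al), c("c3", "c1", "c2"))
  expect_equal(unname(SingleCellExperiment::reducedDim(al, "embedding")),
               unname(toyCoords()[c(3, 1, 2), ]))

  al2 <- alignCells(al, xy)
  expect_equal(as.matrix(SummarizedExperiment::assay(al2)),
               as.matrix(SummarizedExperiment::assay(al)))
  expect_equal(SingleCellExperiment::reducedDim(al2, "embedding"),
               SingleCellExperiment::reducedDim(al, "embedding"))

  disjoint <- xy
  rownames(disjoint) <- paste0("z", 1:3)
  expect_error(alignCells(sce, disjoint), "no cells shared")
})

test_that("filterCellsByGene applies strict and inclusive thresholds", {
  m <- matrix(c(0, 1, 1.5, 3), nrow = 1,
              dimnames = list("CD68", paste0("c", 1:4)))
  sce <- makeSCE(m)
  expect_equal(ncol(filterCellsByGene(sce, "CD68", 1, "greater")), 2L)
  expect_equal(colnames(filterCellsByGene(sce, "CD68", 1, "greater")),
               c("c3", "c4"))
  expect_equal(ncol(filterCellsByGene(sce, "CD68", 0, "greater_equal")), 4L)
  # threshold below any value is the identity on cells
  expect_equal(ncol(filterCellsByGene(sce, "CD68", -Inf, "greater")), 4L)
  expect_error(filterCellsByGene(sce, "CD4", 1), "not found")
})

test_that("composition tables are byte-stable and round-trip within precision", {
  fix <- simulateCells(nClusters = 2, cellsPerCluster = 5, seed = 3)
  comp <- buildCellCompositions(fix$sce, fix$spec)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  writeCompositionTable(comp, f1)
  writeCompositionTable(comp, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  df <- read.csv(f1)
  expect_equal(nrow(df), 10 * nTotalGenes(fix$spec))
  expect_equal(names(df),
               c("cell_id", "gene", "group", "fraction", "intensity", "radius"))
  recomputed <- as.data.frame(comp)
  # agreement to the printed precision (6 decimal places)
  expect_true(all(abs(df$fraction - recomputed$fraction) <= 5e-7))
  expect_true(all(abs(df$intensity - recomputed$intensity) <= 5e-7))
  expect_true(all(abs(df$radius - recomputed$radius) <= 5e-7))

  # empty set: header-only file
  empty <- methods::new("CellCompositionSet",
                        cellIds = character(), genes = character(),
                        groups = character(),
                        fractions = matrix(numeric(), 0, 0),
                        intensities = matrix(numeric(), 0, 0),
                        radii = numeric(), isEmpty = logical(),
                        coords = matrix(numeric(), 0, 2))
  f3 <- tempfile(fileext = ".csv")
  writeCompositionTable(empty, f3)
  expect_equal(readLines(f3),
               "cell_id,gene,group,fraction,intensity,radius")
})
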