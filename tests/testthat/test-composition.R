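test_that("normalizeExpression implements X * nTotal / nGeneList", {
  expect_equal(normalizeExpression(5, 7, 7), 5)    # single list: factor 1
  expect_equal(normalizeExpression(2, 12, 4), 6)
  expect_equal(normalizeExpression(0, 12, 8), 0)
  # linear in x
  expect_equal(normalizeExpression(c(1, 2, 4), 12, 4), c(3, 6, 12))
  expect_error(normalizeExpression(1, 12, 0), "positive integer")
  expect_error(normalizeExpression(-1, 12, 4), "non-negative")
  expect_error(normalizeExpression(1, 3, 4), "nTotal")
})

test_that("computeFractions produces normalized slice shares", {
  spec <- GeneListSpec(list(g = c("A", "B")), "blue")
  expect_equal(computeFractions(c(A = 1, B = 3), spec),
               c(A = 0.25, B = 0.75))

  # all-zero cell: empty, fractions all zero
  expect_equal(computeFractions(c(A = 0, B = 0), spec), c(A = 0, B = 0))

  # matrix input, gene columns reordered to list order
  m <- matrix(c(3, 1, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("B", "A")))
  fr <- computeFractions(m, spec)
  expect_equal(colnames(fr), c("A", "B"))
  expect_equal(unname(fr[1, ]), c(0.25, 0.75))
  expect_equal(unname(fr[2, ]), c(0, 0))

  expect_error(computeFractions(c(A = -1, B = 1), spec), "non-negative")
  expect_error(computeFractions(c(A = 1), spec), "lacks gene")
})

test_that("groups of unequal size get equal total weight at equal expression", {
  # the printed two-list case: sizes 8 and 4, every gene at the same value
  spec <- GeneListSpec(list(class1 = paste0("a", 1:8), class2 = paste0("b", 1:4)),
                       c("blue", "red"))
  x <- setNames(rep(2.5, 12), c(paste0("a", 1:8), paste0("b", 1:4)))
  fr <- computeFractions(x, spec)
  expect_identical(sum(fr[1:8]), 0.5)
  expect_identical(sum(fr[9:12]), 0.5)

  # generalizes to g groups -> 1/g, random sizes and values
  set.seed(11)
  for (i in 1:200) {
    g <- sample(2:5, 1)
    sizes <- sample(1:12, g, replace = TRUE)
    genes <- paste0("G", seq_len(sum(sizes)))
    sp <- GeneListSpec(split(genes, rep(seq_len(g), sizes)), rep("blue", g))
    v <- runif(1, 1e-3, 1e3)
    fr <- computeFractions(setNames(rep(v, sum(sizes)), genes), sp)
    sums <- tapply(fr, rep(seq_len(g), sizes), sum)
    expect_equal(unname(as.vector(sums)), rep(1 / g, g), tolerance = 1e-12)
  }
})

test_that("fractions conserve mass and are scale invariant", {
  set.seed(23)
  for (i in 1:50) {
    rs <- randomSmallSpec(maxGenes = 5)
    x <- matrix(rpois(10 * length(rs$genes), 3), ncol = length(rs$genes),
                dimnames = list(NULL, rs$genes))
    fr <- computeFractions(x, rs$spec)
    tot <- rowSums(fr)
    nonEmpty <- rowSums(x) > 0
    expect_true(all(abs(tot[nonEmpty] - 1) <= 1e-9))
    expect_true(all(tot[!nonEmpty] == 0))
    # multiplying the matrix by c > 0 leaves fractions unchanged
    c0 <- runif(1, 0.1, 17)
    expect_equal(computeFractions(x * c0, rs$spec), fr, tolerance = 1e-12)
  }
})

test_that("fractions match an exact-rational brute-force oracle bit for bit", {
  set.seed(7)
  for (i in 1:500) {
    rs <- randomSmallSpec(maxGenes = 5)
    x <- setNames(sample(0:1000, length(rs$genes), replace = TRUE), rs$genes)
    fr <- computeFractions(x, rs$spec)
    expect_identical(unname(fr), unname(exactFractionOracle(x, rs$nper)))
  }
})

test_that("computeIntensities scales per gene with quantile clipping", {
  m <- matrix(c(1, 2, 4), nrow = 1, dimnames = list("G", paste0("c", 1:3)))
  spec <- GeneListSpec(list(g = "G"), "blue")
  expect_equal(unname(computeIntensities(m, spec, clipQuantile = 1)[, 1]),
               c(0.25, 0.5, 1))

  # constant positive gene: all intensities 1
  mc <- matrix(rep(3, 4), nrow = 1, dimnames = list("G", paste0("c", 1:4)))
  expect_equal(unname(computeIntensities(mc, spec, 0.99)[, 1]), rep(1, 4))

  # all-zero gene: all intensities 0, with a warning naming the gene
  mz <- matrix(0, nrow = 1, ncol = 3, dimnames = list("G", paste0("c", 1:3)))
  expect_warning(iz <- computeIntensities(mz, spec, 0.99), "G")
  expect_equal(unname(iz[, 1]), rep(0, 3))

  # zero expression always maps to intensity 0; mapping is monotone
  set.seed(5)
  v <- c(0, sort(rexp(20, 0.2)))
  mv <- matrix(v, nrow = 1, dimnames = list("G", paste0("c", seq_along(v))))
  iv <- computeIntensities(mv, spec, 0.9)[, 1]
  expect_equal(unname(iv[1]), 0)
  expect_true(all(diff(iv) >= 0))
  expect_true(all(iv >= 0 & iv <= 1))

  expect_error(computeIntensities(m, spec, 0), "clipQuantile")
})

test_that("computeRadius follows sqrt area scaling between rMin and rMax", {
  expect_equal(computeRadius(0, 1, rMin = 1, rMax = 3), 1)
  expect_equal(computeRadius(1, 1, rMin = 1, rMax = 3), 3)
  expect_equal(computeRadius(0.25, 1, rMin = 1, rMax = 3), 2)
  expect_equal(computeRadius(5, 1, rMin = 1, rMax = 3), 3)  # clipped at cap
  # monotone nondecreasing
  r <- computeRadius(seq(0, 2, by = 0.05), 1, rMin = 0.5, rMax = 2)
  expect_true(all(diff(r) >= 0))
  expect_error(computeRadius(1, 0, 1, 3), "positive")
  expect_error(computeRadius(1, 1, 3, 1), "rMax > rMin")
})

test_that("resolveGenes drops or rejects missing genes and recomputes sizes", {
  m <- matrix(1, nrow = 3, ncol = 2,
              dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  spec <- GeneListSpec(list(g1 = c("A", "B", "Z"), g2 = "C"), c("blue", "red"))

  expect_warning(r <- resolveGenes(m, spec, "drop_warn"), "Z")
  expect_equal(unname(groupSizes(r)), c(2L, 1L))
  expect_equal(nTotalGenes(r), 3L)
  expect_error(resolveGenes(m, spec, "error"), "Z")

  # unchanged when everything is present
  ok <- GeneListSpec(list(g1 = c("A", "B"), g2 = "C"), c("blue", "red"))
  expect_equal(groupGenes(resolveGenes(m, ok)), groupGenes(ok))

  # a group losing all its genes is an error under both policies
  gone <- GeneListSpec(list(g1 = "A", g2 = "NOPE"), c("blue", "red"))
  expect_error(resolveGenes(m, gone, "drop_warn"), "no genes left")
  expect_error(resolveGenes(m, gone, "error"), "NOPE")

  # case-insensitive matching adopts the matrix spelling
  ci <- GeneListSpec(list(g1 = c("a", "b")), "blue")
  r2 <- resolveGenes(m, ci, caseInsensitive = TRUE)
  expect_equal(groupGenes(r2)$g1, c("A", "B"))
  expect_error(resolveGenes(m, ci, "drop_warn"), "no genes left")
})

test_that("buildCellCompositions assembles per-cell results in embedding order", {
  sce <- makeSCE(toyMatrix())
  sce <- alignCells(sce, toyCoords())
  spec <- GeneListSpec(list(g1 = "G1", g2 = "G2"), c("blue", "red"))
  comp <- buildCellCompositions(sce, spec, clipQuantile = 1,
                                rMin = 0.05, rMax = 0.2)

  expect_equal(cellIds(comp), c("c1", "c2", "c3"))
  # hand-checked fractions: equal list sizes so fractions = x / sum(x)
  expect_equal(unname(fractions(comp)),
               rbind(c(1, 0), c(0.5, 0.5), c(0, 1)))
  expect_false(any(isEmptyCell(comp)))
  # c3 has the largest total (5), so it gets rMax
  expect_equal(glyphRadii(comp)[3], 0.2)
  # deterministic: identical on repeated calls
  comp2 <- buildCellCompositions(sce, spec, clipQuantile = 1,
                                 rMin = 0.05, rMax = 0.2)
  expect_identical(fractions(comp), fractions(comp2))
  expect_identical(glyphRadii(comp), glyphRadii(comp2))

  # single cell, single gene, positive value: one slice with fraction 1
  one <- makeSCE(matrix(2, 1, 1, dimnames = list("G", "c1")))
  onexy <- matrix(c(0, 0), 1, dimnames = list("c1", c("x", "y")))
  c1 <- buildCellCompositions(alignCells(one, onexy),
                              GeneListSpec(list(g = "G"), "blue"))
  expect_equal(unname(fractions(c1)), matrix(1, 1, 1))

  # zero-expression cells are flagged empty with radius rMin / 2
  zm <- toyMatrix(); zm[, "c1"] <- 0
  zc <- buildCellCompositions(alignCells(makeSCE(zm), toyCoords()), spec,
                              rMin = 0.1, rMax = 0.4)
  expect_true(isEmptyCell(zc)[1])
  expect_equal(glyphRadii(zc)[1], 0.05)
  expect_equal(unname(fractions(zc)[1, ]), c(0, 0))
})
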