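# Shared helpers: tiny in-code fixtures.

# genes x cells SingleCellExperiment from a dense matrix
makeSCE <- function(m) {
  SingleCellExperiment::SingleCellExperiment(assays = list(expression = m))
}

# the 3-cell x 2-gene toy: cells c1..c3, genes G1, G2
toyMatrix <- function() {
  matrix(c(1, 2, 0,
           0, 2, 5),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("G1", "G2"), c("c1", "c2", "c3")))
}

toyCoords <- function() {
  xy <- cbind(x = c(0, 1, 2), y = c(0, 1, 0))
  rownames(xy) <- c("c1", "c2", "c3")
  xy
}

writeToyCsv <- function(m, path, cellsAsRows = FALSE) {
  if (cellsAsRows) m <- t(m)
  idcol <- if (cellsAsRows) "cell" else "gene"
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- idcol
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

writeCoordsCsv <- function(xy, path) {
  df <- data.frame(cell_id = rownames(xy), x = xy[, 1], y = xy[, 2])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

writeGeneList <- function(genes, path = tempfile(fileext = ".txt")) {
  writeLines(genes, path)
  path
}

# independent exact-rational oracle for slice fractions: with integer-valued
# expression x and per-gene group sizes nper, the fraction is the rational
# (x_i / n_i) / sum_j (x_j / n_j) = a_i / A with a_i = x_i * (P / n_i),
# P = prod of group sizes -- all exact integers well below 2^53, so a_i / A
# is a single correctly rounded division of the true rational value.
exactFractionOracle <- function(x, nper) {
  P <- prod(unique(nper))
  # P must be divisible by each n_i; product of unique sizes guarantees it
  a <- x * (P / nper)
  s <- sum(a)
  if (s == 0) return(rep(0, length(x)))
  a / s
}

# random GeneListSpec over at most `maxGenes` genes
randomSmallSpec <- function(maxGenes = 5) {
  repeat {
    g <- sample(1:3, 1)
    sizes <- sample(1:3, g, replace = TRUE)
    if (sum(sizes) <= maxGenes) break
  }
  genes <- paste0("G", seq_len(sum(sizes)))
  list(spec = GeneListSpec(split(genes, rep(seq_len(g), sizes)),
                           rep("blue", g)),
       genes = genes,
       nper = rep(sizes, sizes),
       groupOf = rep(seq_len(g), sizes),
       g = g)
}

uvealListPaths <- function() {
  c(system.file("extdata", "uveal_melanoma_class1.txt", package = "scPies"),
    system.file("extdata", "uveal_melanoma_class2.txt", package = "scPies"))
}
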