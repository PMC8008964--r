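# Synthetic single-cell data generator: Gaussian 2-D blobs with
# negative-binomial gene programs. Test scaffolding, but first-class code.

#' Simulate a small single-cell dataset
#'
#' Generates \code{nClusters} isotropic Gaussian blobs in a 2-D embedding
#' (centers evenly spaced on a circle) and a count matrix in which each
#' cluster has its own \emph{program} genes: negative-binomially distributed
#' with mean \code{programMean} inside the home cluster and
#' \code{backgroundMean} elsewhere. The negative binomial (dispersion
#' parameterized via \code{size}) emulates scRNA-seq overdispersion. Output is
#' fully determined by \code{seed}; the caller's RNG state is untouched.
#'
#' The defaults — 3 clusters of 100 cells, one program gene per cluster,
#' program mean 10 against background mean 0.1 (a 100-fold program-to-
#' background ratio), dispersion 2 — give clearly separated programs whose
#' home-cluster signal dominates the glyph of nearly every cell.
#'
#' @param nClusters number of clusters (>= 1).
#' @param cellsPerCluster cells per cluster (recycled to \code{nClusters}).
#' @param genesPerProgram program genes per cluster.
#' @param programMean mean count of a program gene inside its home cluster.
#' @param backgroundMean mean count elsewhere (0 for strictly
#'   cluster-exclusive programs).
#' @param dispersion negative-binomial \code{size}; smaller = more
#'   overdispersed.
#' @param clusterSpread standard deviation of the Gaussian blobs (embedding
#'   units).
#' @param centerRadius radius of the circle on which cluster centers sit.
#' @param seed integer seed; required for reproducibility.
#' @return a list with elements \code{sce} (an aligned
#'   \code{SingleCellExperiment} with assay \code{"expression"}, reduced
#'   dimension \code{"embedding"} and \code{colData} column \code{cluster}),
#'   \code{spec} (a \code{\link{GeneListSpec}} with one group per cluster
#'   program) and \code{clusters} (a cell/cluster data.frame).
#' @export
#' @examples
#' fix <- simulateCells(seed = 1)
#' dim(fix$sce)
#' groupSizes(fix$spec)
simulateCells <- function(nClusters = 3, cellsPerCluster = 100,
                          genesPerProgram = 1, programMean = 10,
                          backgroundMean = 0.1, dispersion = 2,
                          clusterSpread = 0.5, centerRadius = 5, seed = 1) {
  stopifnot(nClusters >= 1, all(cellsPerCluster >= 1), genesPerProgram >= 1,
            programMean > 0, backgroundMean >= 0, dispersion > 0,
            clusterSpread > 0, centerRadius > 0)
  nPer <- rep_len(as.integer(cellsPerCluster), nClusters)
  nCells <- sum(nPer)
  clusterOf <- rep(seq_len(nClusters), nPer)
  cellIds <- sprintf("cell%04d", seq_len(nCells))
  labels <- sprintf("C%d", clusterOf)

  geneIds <- as.vector(vapply(seq_len(nClusters), function(k)
    sprintf("PRG%d.%d", k, seq_len(genesPerProgram)),
    character(genesPerProgram)))
  geneCluster <- rep(seq_len(nClusters), each = genesPerProgram)

  withSeed(seed, {
    ang <- 2 * pi * (seq_len(nClusters) - 1) / nClusters
    centers <- centerRadius * cbind(cos(ang), sin(ang))
    coords <- centers[clusterOf, , drop = FALSE] +
      matrix(stats::rnorm(2 * nCells, sd = clusterSpread), ncol = 2)
    dimnames(coords) <- list(cellIds, c("x", "y"))

    counts <- matrix(0, nrow = length(geneIds), ncol = nCells,
                     dimnames = list(geneIds, cellIds))
    for (g in seq_along(geneIds)) {
      mu <- ifelse(clusterOf == geneCluster[g], programMean, backgroundMean)
      counts[g, ] <- stats::rnbinom(nCells, size = dispersion, mu = mu)
    }
    counts
  })

  rules <- rep_len(c("winter", "autumn", "cool", "viridis", "plasma", "heat"),
                   nClusters)
  spec <- GeneListSpec(
    genes = split(geneIds, geneCluster),
    colorRules = rules,
    groupNames = sprintf("cluster%d_program", seq_len(nClusters))
  )

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(expression = counts))
  sce <- alignCells(sce, coords,
                    clusters = setNames(labels, cellIds))
  list(sce = sce,
       spec = spec,
       clusters = data.frame(cell_id = cellIds, cluster = labels,
                             stringsAsFactors = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Exports a \code{\link{simulateCells}} result as plain-text files:
#' expression (CSV or MatrixMarket triple), coordinates, cluster assignments
#' and one gene-list file per program, plus a \code{config.yaml} that the
#' command-line interface can consume directly.
#'
#' @param fix a list from \code{\link{simulateCells}}.
#' @param dir output directory (created if needed).
#' @param format \code{"csv"} or \code{"mtx"} for the expression matrix.
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(fix, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sce <- fix$sce
  if (format == "mtx") {
    exprPath <- file.path(dir, "matrix.mtx")
    writeExpressionMatrix(sce, exprPath, format = "matrixmarket")
  } else {
    exprPath <- file.path(dir, "expression.csv")
    writeExpressionMatrix(sce, exprPath, format = "delimited")
  }
  coords <- SingleCellExperiment::reducedDim(sce, "embedding")
  df <- data.frame(cell_id = colnames(sce), x = coords[, 1], y = coords[, 2],
                   stringsAsFactors = FALSE)
  write.csv(df, file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  write.csv(fix$clusters, file.path(dir, "clusters.csv"), row.names = FALSE,
            quote = FALSE)
  listPaths <- character()
  gg <- groupGenes(fix$spec)
  for (i in seq_along(gg)) {
    p <- file.path(dir, sprintf("gene_list_%s.txt", names(gg)[i]))
    writeLines(gg[[i]], p)
    listPaths <- c(listPaths, p)
  }
  cfg <- list(
    expression = exprPath,
    format = if (format == "mtx") "mtx" else "csv",
    orientation = "genes-rows",
    coords = file.path(dir, "coords.csv"),
    `gene-list` = as.list(listPaths),
    color = as.list(unname(colorRules(fix$spec))),
    clusters = file.path(dir, "clusters.csv"),
    out = file.path(dir, "figure.svg"),
    `out-format` = "svg"
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
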