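# Readers/writers for expression matrices, embeddings, gene lists and
# cluster assignments, plus cell alignment and threshold filtering.

#' Read a cell x gene expression matrix
#'
#' Reads either a dense delimited export (CSV/TSV, header row plus an
#' identifier column) or a MatrixMarket triple (\code{matrix.mtx} with sibling
#' \code{genes.tsv}/\code{features.tsv} and \code{barcodes.tsv}) into a
#' \code{\link[SingleCellExperiment]{SingleCellExperiment}} with a single
#' assay \code{"expression"} (genes as rows, the Bioconductor convention).
#' Values are used as provided (raw or normalized counts); they must be
#' non-negative and finite, and identifiers must be unique.
#'
#' @param path path to the CSV/TSV file or the \code{.mtx} file.
#' @param orientation orientation of the file on disk: \code{"genes_as_rows"}
#'   (default; the common single-cell export convention) or
#'   \code{"cells_as_rows"}.
#' @param format \code{"auto"} (by extension), \code{"delimited"} or
#'   \code{"matrixmarket"}.
#' @param genesFile,barcodesFile optional explicit paths to the MatrixMarket
#'   sibling files; by default \code{genes.tsv} (or \code{features.tsv}) and
#'   \code{barcodes.tsv} next to the \code{.mtx} file.
#' @return a \code{SingleCellExperiment} (genes x cells, assay
#'   \code{"expression"}).
#' @seealso \code{\link{alignCells}}, \code{\link{writeExpressionMatrix}}
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("gene,c1,c2,c3", "G1,1,2,0", "G2,0,2,5"), f)
#' sce <- readExpressionMatrix(f)
#' dim(sce)
readExpressionMatrix <- function(path,
                                 orientation = c("genes_as_rows", "cells_as_rows"),
                                 format = c("auto", "delimited", "matrixmarket"),
                                 genesFile = NULL, barcodesFile = NULL) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path))
    stopf("expression file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", path, ignore.case = TRUE))
      "matrixmarket" else "delimited"

  if (format == "matrixmarket") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stopf("malformed MatrixMarket file '%s': %s",
                                            path, conditionMessage(e)))
    dir <- dirname(path)
    if (is.null(genesFile)) {
      cand <- file.path(dir, c("genes.tsv", "features.tsv"))
      genesFile <- cand[file.exists(cand)][1]
      if (is.na(genesFile))
        stopf("no genes.tsv/features.tsv sibling found for %s", path)
    }
    if (is.null(barcodesFile))
      barcodesFile <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genesFile)) stopf("genes file not found: %s", genesFile)
    if (!file.exists(barcodesFile)) stopf("barcodes file not found: %s", barcodesFile)
    gtab <- read.delim(genesFile, header = FALSE, stringsAsFactors = FALSE)
    # 10x-style features files carry (id, symbol, ...); gene lists use symbols
    geneIds <- as.character(if (ncol(gtab) >= 2) gtab[[2]] else gtab[[1]])
    cellIds <- as.character(read.delim(barcodesFile, header = FALSE,
                                       stringsAsFactors = FALSE)[[1]])
    m <- methods::as(m, "CsparseMatrix")
    rowIds <- if (orientation == "genes_as_rows") geneIds else cellIds
    colIds <- if (orientation == "genes_as_rows") cellIds else geneIds
    if (nrow(m) != length(rowIds) || ncol(m) != length(colIds))
      stopf("MatrixMarket dimensions (%d x %d) do not match genes/barcodes files (%d, %d)",
            nrow(m), ncol(m), length(geneIds), length(cellIds))
    dimnames(m) <- list(rowIds, colIds)
  } else {
    sep <- delimFor(path)
    df <- tryCatch(
      read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stopf("malformed delimited file '%s': %s",
                                path, conditionMessage(e)))
    if (ncol(df) < 2)
      stopf("expression file '%s' needs an identifier column plus at least one value column",
            path)
    ids <- as.character(df[[1]])
    vals <- df[, -1, drop = FALSE]
    nonnum <- !vapply(vals, is.numeric, logical(1))
    if (any(nonnum))
      stopf("non-numeric expression column(s) in '%s': %s", path,
            paste(names(vals)[nonnum], collapse = ", "))
    m <- as.matrix(vals)
    rownames(m) <- ids
  }

  if (orientation == "cells_as_rows") m <- Matrix::t(m)
  checkExpressionValues(m)
  SingleCellExperiment::SingleCellExperiment(assays = list(expression = m))
}

#' Write an expression matrix
#'
#' Writes the expression assay as a delimited file (genes as rows, identifier
#' column \code{gene}) or as a MatrixMarket triple
#' (\code{.mtx} + \code{genes.tsv} + \code{barcodes.tsv}). Primarily used to
#' export simulated fixtures.
#'
#' @param x a \code{SingleCellExperiment}/\code{SummarizedExperiment} or a
#'   genes x cells matrix with dimnames.
#' @param path output path (the \code{.mtx} path for MatrixMarket; siblings
#'   are written next to it).
#' @param format \code{"delimited"} or \code{"matrixmarket"}.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path,
                                  format = c("delimited", "matrixmarket")) {
  format <- match.arg(format)
  m <- exprValues(x)
  if (format == "matrixmarket") {
    Matrix::writeMM(methods::as(methods::as(m, "dMatrix"), "CsparseMatrix"), path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- delimFor(path)
    dense <- as.matrix(m)
    df <- data.frame(gene = rownames(dense), dense, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read 2-D embedding coordinates
#'
#' Reads a delimited export of per-cell 2-D coordinates (UMAP, t-SNE, ...)
#' with header columns \code{cell_id}, \code{x}, \code{y}. Row order is
#' preserved: it defines the deterministic cell order of the plot.
#'
#' @param path path to a CSV/TSV file.
#' @return a numeric matrix (cells x 2, columns \code{x}, \code{y}) whose
#'   rownames are the cell identifiers, in file order.
#' @seealso \code{\link{alignCells}}
#' @export
readCoordinates <- function(path) {
  if (!file.exists(path))
    stopf("coordinates file not found: %s", path)
  df <- read.csv(path, sep = delimFor(path), check.names = FALSE,
                 stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("coordinates file '%s' lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  ids <- as.character(df$cell_id)
  if (anyDuplicated(ids))
    stopf("duplicate cell identifiers in coordinates file '%s'", path)
  xy <- cbind(x = df$x, y = df$y)
  if (!is.numeric(xy))
    stopf("non-numeric coordinates in '%s'", path)
  if (any(!is.finite(xy)))
    stopf("non-finite coordinate(s) in '%s'", path)
  rownames(xy) <- ids
  xy
}

#' Read marker gene lists
#'
#' Reads one or more plain-text gene lists (one symbol per line; blank lines
#' and lines starting with \code{#} are ignored) and pairs them positionally
#' with color rules into a \code{\link{GeneListSpec}}. Within-group gene order
#' follows file line order; group order follows argument order.
#'
#' @param paths character vector of gene-list file paths.
#' @param colorRules character vector of color rules (one per file): a hex
#'   color \code{"#RRGGBB"}, an R color name, or a colormap name from
#'   \code{\link{paletteRegistry}}.
#' @param groupNames optional group names; defaults to the file base names.
#' @return a \code{\link{GeneListSpec}}.
#' @export
#' @examples
#' f1 <- system.file("extdata", "uveal_melanoma_class1.txt", package = "scPies")
#' f2 <- system.file("extdata", "uveal_melanoma_class2.txt", package = "scPies")
#' spec <- readGeneLists(c(f1, f2), c("blue", "red"))
#' groupSizes(spec)
readGeneLists <- function(paths, colorRules, groupNames = NULL) {
  if (length(paths) != length(colorRules))
    stopf("need exactly one color rule per gene-list file (%d files, %d rules)",
          length(paths), length(colorRules))
  if (length(paths) == 0)
    stopf("at least one gene-list file is required")
  if (is.null(groupNames))
    groupNames <- sub("\\.[^.]*$", "", basename(paths))
  genes <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p)) stopf("gene-list file not found: %s", p)
    ln <- trimws(readLines(p, warn = FALSE))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    if (length(ln) == 0)
      stopf("gene-list file '%s' contains no genes", p)
    if (anyDuplicated(ln))
      stopf("gene-list file '%s' contains duplicate gene(s): %s", p,
            paste(unique(ln[duplicated(ln)]), collapse = ", "))
    ln
  })
  GeneListSpec(genes = genes, colorRules = colorRules, groupNames = groupNames)
}

#' Read a per-cell cluster assignment table
#'
#' @param path delimited file with header columns \code{cell_id} and
#'   \code{cluster}.
#' @return a data.frame with character columns \code{cell_id}, \code{cluster}.
#' @seealso \code{\link{summarizeClusters}}
#' @export
readClusterAssignments <- function(path) {
  if (!file.exists(path))
    stopf("cluster assignment file not found: %s", path)
  df <- read.csv(path, sep = delimFor(path), check.names = FALSE,
                 stringsAsFactors = FALSE)
  need <- c("cell_id", "cluster")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("cluster file '%s' lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stopf("duplicate cell identifiers in cluster file '%s'", path)
  data.frame(cell_id = as.character(df$cell_id),
             cluster = as.character(df$cluster), stringsAsFactors = FALSE)
}

#' Align an expression matrix with an embedding
#'
#' Restricts the expression matrix and the embedding to their common cells,
#' in embedding (file) order, and attaches the coordinates as the
#' \code{"embedding"} reduced dimension. Cells present in only one input are
#' dropped with a message. Optionally attaches per-cell cluster labels
#' (\code{colData} column \code{cluster}); cells without a label get
#' \code{NA}. The operation is idempotent.
#'
#' @param sce a \code{SingleCellExperiment} from
#'   \code{\link{readExpressionMatrix}}.
#' @param embedding coordinate matrix from \code{\link{readCoordinates}} (or
#'   any cells x 2 numeric matrix with unique rownames).
#' @param clusters optional assignment from
#'   \code{\link{readClusterAssignments}} (or a named character vector). All
#'   assigned cells must exist in the embedding.
#' @return the aligned \code{SingleCellExperiment} with
#'   \code{reducedDim(., "embedding")} set.
#' @export
alignCells <- function(sce, embedding, clusters = NULL) {
  if (is.data.frame(embedding)) {
    xy <- cbind(x = embedding$x, y = embedding$y)
    rownames(xy) <- as.character(embedding$cell_id)
    embedding <- xy
  }
  if (is.null(rownames(embedding)) || ncol(embedding) != 2L)
    stopf("embedding must be a cells x 2 matrix with cell identifiers as rownames")
  if (any(!is.finite(embedding)))
    stopf("embedding contains non-finite coordinates")
  if (anyDuplicated(rownames(embedding)))
    stopf("duplicate cell identifiers in embedding")
  ids <- rownames(embedding)
  keep <- ids[ids %in% colnames(sce)]
  if (length(keep) == 0)
    stopf("no cells shared between expression matrix and embedding")
  dropE <- length(ids) - length(keep)
  dropM <- ncol(sce) - length(keep)
  if (dropE > 0)
    message(sprintf("alignCells: dropped %d embedded cell(s) absent from the expression matrix",
                    dropE))
  if (dropM > 0)
    message(sprintf("alignCells: dropped %d expression cell(s) absent from the embedding",
                    dropM))
  out <- sce[, keep]
  SingleCellExperiment::reducedDim(out, "embedding") <-
    unname(embedding[keep, , drop = FALSE])

  if (!is.null(clusters)) {
    if (is.data.frame(clusters))
      clusters <- setNames(as.character(clusters$cluster),
                           as.character(clusters$cell_id))
    unknown <- setdiff(names(clusters), ids)
    if (length(unknown))
      stopf("cluster assignment refers to cell(s) absent from the embedding: %s%s",
            paste(head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
    SummarizedExperiment::colData(out)$cluster <-
      unname(clusters[match(keep, names(clusters))])
  }
  out
}

#' Filter cells by the expression of one gene
#'
#' Keeps the cells whose expression of \code{gene} exceeds (or reaches) a
#' threshold, e.g. extracting a macrophage population as the cells with CD68
#' expression above 1. The gene set is unchanged.
#'
#' @param x a \code{SingleCellExperiment}/\code{SummarizedExperiment} or a
#'   genes x cells matrix.
#' @param gene gene identifier (must be present).
#' @param threshold numeric threshold.
#' @param mode \code{"greater"} (strict, the default) or
#'   \code{"greater_equal"}.
#' @return the filtered object, same class as \code{x}.
#' @export
filterCellsByGene <- function(x, gene, threshold,
                              mode = c("greater", "greater_equal")) {
  mode <- match.arg(mode)
  m <- exprValues(x)
  if (!gene %in% rownames(m))
    stopf("gene '%s' not found in the expression matrix", gene)
  v <- as.numeric(m[gene, ])
  keep <- if (mode == "greater") v > threshold else v >= threshold
  x[, keep]
}

#' Write a composition table
#'
#' Writes one CSV row per (cell, gene) with columns
#' \code{cell_id,gene,group,fraction,intensity,radius}. Reals are printed
#' with 6 decimal places so repeated runs are byte-identical.
#'
#' @param comp a \code{\link{CellCompositionSet}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCompositionTable <- function(comp, path) {
  df <- as.data.frame(comp)
  lines <- c("cell_id,gene,group,fraction,intensity,radius",
             if (nrow(df)) sprintf("%s,%s,%s,%.6f,%.6f,%.6f",
                                   df$cell_id, df$gene, df$group,
                                   df$fraction, df$intensity, df$radius))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
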