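# Cluster-aggregated "big pies" mode.

#' Summarize expression per cell cluster
#'
#' Builds one summary per cluster: the arithmetic mean expression of the
#' selected genes over member cells, the coordinate centroid, the member
#' count, and the composition of the mean vector (slice fractions via
#' \code{\link{computeFractions}}; since fractions are scale invariant, the
#' composition of the mean equals the composition of the summed expression).
#' Per-cluster intensities are computed against the same per-gene clip values
#' as the cell-level plot, so cell and cluster figures are color-comparable.
#' Summaries are ordered by decreasing cell count (ties by label).
#'
#' @param sce an aligned \code{SingleCellExperiment} with reduced dimension
#'   \code{"embedding"} (see \code{\link{alignCells}}).
#' @param spec a \code{\link{GeneListSpec}}.
#' @param clusters per-cell labels: a data.frame from
#'   \code{\link{readClusterAssignments}}, a named vector, or \code{NULL} to
#'   use \code{colData(sce)$cluster}. Assigned cells must exist in \code{sce};
#'   cells with \code{NA} labels are ignored. Empty clusters (unused factor
#'   levels) are dropped with a warning.
#' @param clipQuantile quantile in (0, 1] for intensity clipping (shared with
#'   cell mode).
#' @param rMin,rMax radius bounds for the big pies (embedding units);
#'   \code{rMax = NULL} defaults to 10\% of the larger embedding extent,
#'   \code{rMin} defaults to 0 so pie areas are exactly proportional to cell
#'   counts (see \code{\link{clusterRadii}}).
#' @param missingGenePolicy,caseInsensitive passed to
#'   \code{\link{resolveGenes}}.
#' @return a \code{\link{ClusterSummarySet}}.
#' @export
summarizeClusters <- function(sce, spec, clusters = NULL, clipQuantile = 0.99,
                              rMin = 0, rMax = NULL,
                              missingGenePolicy = c("drop_warn", "error"),
                              caseInsensitive = FALSE) {
  if (!methods::is(sce, "SingleCellExperiment") ||
      !"embedding" %in% SingleCellExperiment::reducedDimNames(sce))
    stopf("input must be a SingleCellExperiment with an 'embedding' reduced dimension; run alignCells() first")
  coords <- as.matrix(SingleCellExperiment::reducedDim(sce, "embedding"))

  levAll <- NULL
  if (is.null(clusters)) {
    if (!"cluster" %in% names(SummarizedExperiment::colData(sce)))
      stopf("no cluster assignment: pass `clusters` or align with one")
    raw <- SummarizedExperiment::colData(sce)$cluster
    if (is.factor(raw)) levAll <- levels(raw)
    labels <- as.character(raw)
  } else {
    if (is.data.frame(clusters))
      clusters <- setNames(clusters$cluster, as.character(clusters$cell_id))
    if (is.factor(clusters)) {
      levAll <- levels(clusters)
      clusters <- setNames(as.character(clusters), names(clusters))
    } else {
      clusters <- setNames(as.character(clusters), names(clusters))
    }
    unknown <- setdiff(names(clusters), colnames(sce))
    if (length(unknown))
      stopf("cluster assignment refers to unknown cell(s): %s%s",
            paste(head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
    labels <- unname(clusters[match(colnames(sce), names(clusters))])
  }

  assigned <- !is.na(labels)
  if (!any(assigned))
    stopf("no cell carries a cluster label")
  if (is.null(levAll)) levAll <- unique(labels[assigned])
  lev <- levAll
  counts <- table(factor(labels[assigned], levels = lev))
  if (any(counts == 0)) {
    warningf("dropped empty cluster(s): %s",
             paste(names(counts)[counts == 0], collapse = ", "))
    lev <- names(counts)[counts > 0]
  }

  rspec <- resolveGenes(sce, spec, policy = missingGenePolicy,
                        caseInsensitive = caseInsensitive)
  genes <- unlist(rspec@genes, use.names = FALSE)
  groups <- rep(rspec@groupNames, lengths(rspec@genes))
  expr <- as.matrix(exprValues(sce)[genes, , drop = FALSE])

  k <- length(lev)
  meanExpr <- matrix(0, nrow = k, ncol = length(genes),
                     dimnames = list(lev, genes))
  centroids <- matrix(0, nrow = k, ncol = 2)
  n <- integer(k)
  for (i in seq_len(k)) {
    member <- assigned & labels == lev[i]
    n[i] <- sum(member)
    meanExpr[i, ] <- rowMeans(expr[, member, drop = FALSE])
    centroids[i, ] <- colMeans(coords[member, , drop = FALSE])
  }

  ord <- order(-n, lev)
  lev <- lev[ord]; n <- n[ord]
  meanExpr <- meanExpr[ord, , drop = FALSE]
  centroids <- centroids[ord, , drop = FALSE]

  fr <- computeFractions(meanExpr, rspec)
  isEmpty <- rowSums(meanExpr) == 0

  # intensity of the mean vector on the cell-level clip scale
  inten <- matrix(0, nrow = k, ncol = length(genes))
  for (j in seq_along(genes)) {
    v <- expr[j, ]
    pos <- v[v > 0]
    if (length(pos) == 0) next
    q <- quantile(pos, clipQuantile, names = FALSE, type = 7)
    inten[, j] <- pmin(meanExpr[, j] / q, 1)
  }

  ext <- apply(coords, 2, function(v) diff(range(v)))
  if (is.null(rMax)) {
    rMax <- 0.10 * max(ext)
    if (rMax <= 0) rMax <- 1
  }
  radii <- clusterRadii(n, rMin = rMin, rMax = rMax)

  comp <- methods::new("CellCompositionSet",
                       cellIds = lev, genes = genes, groups = groups,
                       fractions = unname(fr), intensities = inten,
                       radii = radii, isEmpty = isEmpty, coords = centroids)
  dimnames(meanExpr) <- list(NULL, genes)
  methods::new("ClusterSummarySet", labels = lev, nCells = as.integer(n),
               centroids = centroids, meanExpression = meanExpr,
               composition = comp)
}

#' Cluster pie radii from cell counts
#'
#' Sizes the "big pies" by member count with square-root scaling,
#' \deqn{r_k = r_{min} + (r_{max} - r_{min}) \sqrt{n_k / n_{max}},}
#' so that with \code{rMin = 0} the pie \emph{areas} are exactly proportional
#' to cluster cell counts. The largest cluster always gets \code{rMax}.
#'
#' @param x a \code{\link{ClusterSummarySet}} or a vector of positive cell
#'   counts.
#' @param rMin,rMax radius bounds, \code{rMax > rMin >= 0}.
#' @return numeric radii, one per cluster.
#' @export
#' @examples
#' clusterRadii(c(100, 25), rMin = 0, rMax = 2)  # 2 1
clusterRadii <- function(x, rMin = 0, rMax) {
  n <- if (methods::is(x, "ClusterSummarySet")) x@nCells else as.numeric(x)
  if (length(n) == 0)
    stopf("at least one cluster is required")
  if (any(n < 1))
    stopf("cluster cell counts must be positive")
  if (!(rMax > rMin && rMin >= 0))
    stopf("must have rMax > rMin >= 0")
  rMin + (rMax - rMin) * sqrt(n / max(n))
}
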