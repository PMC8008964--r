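# The numeric core: list-size normalization, slice fractions, intensities
# and glyph radii.

#' List-size normalization of an expression value
#'
#' Rescales an expression value \eqn{X} of a gene belonging to a list of
#' \eqn{N_{list}} genes, out of \eqn{N_{total}} genes across all lists, to
#' \deqn{X_{norm} = X \cdot N_{total} / N_{list}.}
#' Under this rescaling, gene lists of unequal length receive equal total
#' weight in a pie glyph: if every gene is expressed at a common value, each
#' of \eqn{g} lists contributes exactly \eqn{1/g} of the pie.
#'
#' @param x non-negative expression value(s).
#' @param nTotal total number of genes across all lists (positive integer).
#' @param nGeneList number of genes in this gene's list (positive integer,
#'   at most \code{nTotal}).
#' @return \code{x * nTotal / nGeneList}.
#' @export
#' @examples
#' normalizeExpression(5, 7, 7)   # single list: factor 1
#' normalizeExpression(2, 12, 4)  # 6
normalizeExpression <- function(x, nTotal, nGeneList) {
  if (length(nGeneList) != 1 || is.na(nGeneList) || nGeneList < 1 ||
      nGeneList != as.integer(nGeneList))
    stopf("nGeneList must be a positive integer (got %s)", format(nGeneList))
  if (length(nTotal) != 1 || is.na(nTotal) || nTotal < nGeneList ||
      nTotal != as.integer(nTotal))
    stopf("nTotal must be an integer >= nGeneList")
  if (any(is.na(x)) || any(x < 0))
    stopf("expression values must be non-negative")
  # factor first: the single-list case (nTotal == nGeneList) is exactly x
  x * (nTotal / nGeneList)
}

# Per-gene weight factors implementing the list-size normalization on a
# common integer denominator: factor_i = nTotal * L / n_i with L the least
# common multiple of the group sizes. Proportional to nTotal / n_i, so the
# resulting fractions are identical; using the common multiple keeps the
# weights of integer-valued inputs exactly representable, so each fraction is
# a single correctly-rounded division.
normalizationFactors <- function(spec) {
  sizes <- lengths(spec@genes)
  if (length(sizes) == 0)
    stopf("gene list specification contains no groups")
  L <- lcmAll(sizes)
  nTot <- sum(sizes)
  rep(nTot * (L / sizes), sizes)
}

#' Slice fractions of one or many cells
#'
#' Computes each gene's share of a cell's total normalized expression:
#' \eqn{fraction_i = X_{norm,i} / \sum_j X_{norm,j}} with
#' \eqn{X_{norm} = X \cdot N_{total}/N_{list}} (see
#' \code{\link{normalizeExpression}}). Fractions of a cell whose selected
#' genes are all zero are all zero (an \emph{empty} cell).
#'
#' @param x a named non-negative vector of per-gene expression for one cell,
#'   or a cells x genes matrix with gene column names. Must cover every gene
#'   in \code{spec} (resolve against the matrix first with
#'   \code{\link{resolveGenes}}).
#' @param spec a \code{\link{GeneListSpec}} (resolved).
#' @return fractions in concatenated gene-list order: a named vector for
#'   vector input, a cells x genes matrix for matrix input. Non-empty rows
#'   sum to 1.
#' @export
#' @examples
#' spec <- GeneListSpec(list(g = c("A", "B")), "blue")
#' computeFractions(c(A = 1, B = 3), spec)  # 0.25 0.75
computeFractions <- function(x, spec) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1, dimnames = list(NULL, names(x))) else x
  genes <- unlist(spec@genes, use.names = FALSE)
  if (is.null(colnames(m)))
    stopf("expression input must carry gene names")
  missing <- setdiff(genes, colnames(m))
  if (length(missing))
    stopf("expression input lacks gene(s): %s", paste(missing, collapse = ", "))
  m <- m[, genes, drop = FALSE]
  if (any(is.na(m)) || any(m < 0))
    stopf("expression values must be non-negative")
  w <- sweep(m, 2L, normalizationFactors(spec), `*`)
  tot <- rowSums(w)
  fr <- w / tot
  fr[tot == 0, ] <- 0
  dimnames(fr) <- list(rownames(m), genes)
  if (vec) fr[1, ] else fr
}

#' Per-gene color intensities
#'
#' For each selected gene, scales expression to [0, 1] against a per-gene
#' reference value: the \code{clipQuantile} quantile of that gene's
#' \emph{positive} values over the plotted cells. Values at or above the
#' reference are clipped to 1; zero expression maps to intensity 0; the
#' mapping is monotone nondecreasing. A gene with no positive values gets
#' intensity 0 everywhere (with a warning).
#'
#' @param x a \code{SingleCellExperiment}/\code{SummarizedExperiment} or a
#'   genes x cells matrix covering the resolved genes.
#' @param spec a resolved \code{\link{GeneListSpec}}.
#' @param clipQuantile quantile in (0, 1] of positive values used as the
#'   per-gene reference; 1 uses the maximum, the default 0.99 resists
#'   outliers.
#' @return a cells x genes intensity matrix in [0, 1], genes in concatenated
#'   list order.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 4), nrow = 1, dimnames = list("G", c("c1", "c2", "c3")))
#' spec <- GeneListSpec(list(g = "G"), "blue")
#' computeIntensities(m, spec, clipQuantile = 1)  # 0.25 0.5 1
computeIntensities <- function(x, spec, clipQuantile = 0.99) {
  if (!(clipQuantile > 0 && clipQuantile <= 1))
    stopf("clipQuantile must lie in (0, 1]")
  m <- exprValues(x)
  genes <- unlist(spec@genes, use.names = FALSE)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stopf("expression matrix lacks gene(s): %s", paste(missing, collapse = ", "))
  sub <- as.matrix(m[genes, , drop = FALSE])
  if (any(sub < 0))
    stopf("expression values must be non-negative")
  out <- matrix(0, nrow = ncol(sub), ncol = length(genes),
                dimnames = list(colnames(sub), genes))
  for (j in seq_along(genes)) {
    v <- sub[j, ]
    pos <- v[v > 0]
    if (length(pos) == 0) {
      warningf("gene '%s' has no positive expression; its intensity is 0 for all cells",
               genes[j])
      next
    }
    q <- quantile(pos, clipQuantile, names = FALSE, type = 7)
    out[, j] <- pmin(v / q, 1)
  }
  out
}

#' Glyph radius from total expression
#'
#' Maps a cell's total normalized expression to a glyph radius with
#' square-root scaling, so glyph \emph{area} grows proportionally to total
#' expression up to the cap:
#' \deqn{r = r_{min} + (r_{max} - r_{min}) \sqrt{\min(T / T_{max}, 1)}.}
#'
#' @param total non-negative total normalized expression (vectorized).
#' @param totalMax positive cap; totals at or above it map to \code{rMax}.
#' @param rMin,rMax radius bounds in embedding units, \code{rMax > rMin > 0}.
#' @return radii, same length as \code{total}; \code{computeRadius(0, ...)}
#'   is \code{rMin}.
#' @export
#' @examples
#' computeRadius(c(0, 0.25, 1), totalMax = 1, rMin = 1, rMax = 3)  # 1 2 3
computeRadius <- function(total, totalMax, rMin, rMax) {
  if (length(totalMax) != 1 || is.na(totalMax) || totalMax <= 0)
    stopf("totalMax must be a single positive number")
  if (!(rMax > rMin && rMin > 0))
    stopf("must have rMax > rMin > 0")
  if (any(is.na(total)) || any(total < 0))
    stopf("total expression must be non-negative")
  rMin + (rMax - rMin) * sqrt(pmin(total / totalMax, 1))
}

#' Resolve gene lists against an expression matrix
#'
#' Removes (or reports) genes absent from the matrix so that all downstream
#' list sizes (\eqn{N_{total}}, \eqn{N_{list}}) reflect the genes actually
#' available. A group that loses all its genes is an error under either
#' policy.
#'
#' @param x a \code{SingleCellExperiment}/\code{SummarizedExperiment} or a
#'   genes x cells matrix.
#' @param spec a \code{\link{GeneListSpec}}.
#' @param policy \code{"drop_warn"} (default): drop missing genes with a
#'   warning naming them; \code{"error"}: fail on any missing gene.
#' @param caseInsensitive match gene symbols case-insensitively; resolved
#'   lists adopt the matrix's spelling. Default is exact (case-sensitive)
#'   matching, which does not hide real mismatches.
#' @return the resolved \code{GeneListSpec}.
#' @export
resolveGenes <- function(x, spec, policy = c("drop_warn", "error"),
                         caseInsensitive = FALSE) {
  policy <- match.arg(policy)
  rn <- rownames(exprValues(x))
  lookup <- if (caseInsensitive) toupper(rn) else rn
  resolved <- list()
  kept <- character()
  rules <- character()
  droppedAll <- character()
  for (i in seq_along(spec@groupNames)) {
    g <- spec@genes[[i]]
    key <- if (caseInsensitive) toupper(g) else g
    idx <- match(key, lookup)
    missing <- g[is.na(idx)]
    droppedAll <- c(droppedAll, missing)
    if (length(missing) && policy == "error")
      stopf("gene(s) not found in the expression matrix: %s",
            paste(missing, collapse = ", "))
    present <- rn[idx[!is.na(idx)]]
    if (length(present) == 0)
      stopf("group '%s' has no genes left after resolving against the matrix",
            spec@groupNames[i])
    resolved <- c(resolved, list(present))
    kept <- c(kept, spec@groupNames[i])
    rules <- c(rules, spec@colorRules[i])
  }
  if (length(droppedAll))
    warningf("dropped %d gene(s) absent from the expression matrix: %s",
             length(droppedAll), paste(droppedAll, collapse = ", "))
  GeneListSpec(genes = resolved, colorRules = rules, groupNames = kept)
}

#' Build per-cell compositions for an aligned experiment
#'
#' The deterministic numeric pipeline behind a cell-mode plot: resolves the
#' gene lists, computes slice fractions (\code{\link{computeFractions}}),
#' per-gene intensities (\code{\link{computeIntensities}}) and glyph radii
#' (\code{\link{computeRadius}}) for every embedded cell, in embedding order.
#' The radius cap is the \code{clipQuantile} quantile of the positive
#' per-cell totals (one robustness knob shared with the intensity clipping).
#' Zero-expression cells are flagged empty and get radius \code{rMin/2}.
#'
#' @param sce an aligned \code{SingleCellExperiment} (see
#'   \code{\link{alignCells}}) with reduced dimension \code{"embedding"}.
#' @param spec a \code{\link{GeneListSpec}}.
#' @param clipQuantile quantile in (0, 1] for intensity and total clipping.
#' @param rMin,rMax glyph radius bounds in embedding units; \code{NULL}
#'   derives \code{rMax} as 1.5\% of the larger embedding extent and
#'   \code{rMin} as \code{rMax/4}.
#' @param missingGenePolicy,caseInsensitive passed to
#'   \code{\link{resolveGenes}}.
#' @return a \code{\link{CellCompositionSet}}, one entry per embedded cell.
#' @export
buildCellCompositions <- function(sce, spec, clipQuantile = 0.99,
                                  rMin = NULL, rMax = NULL,
                                  missingGenePolicy = c("drop_warn", "error"),
                                  caseInsensitive = FALSE) {
  if (!methods::is(sce, "SingleCellExperiment") ||
      !"embedding" %in% SingleCellExperiment::reducedDimNames(sce))
    stopf("input must be a SingleCellExperiment with an 'embedding' reduced dimension; run alignCells() first")
  coords <- SingleCellExperiment::reducedDim(sce, "embedding")
  rspec <- resolveGenes(sce, spec, policy = missingGenePolicy,
                        caseInsensitive = caseInsensitive)
  genes <- unlist(rspec@genes, use.names = FALSE)
  groups <- rep(rspec@groupNames, lengths(rspec@genes))
  expr <- as.matrix(exprValues(sce)[genes, , drop = FALSE])
  X <- t(expr)

  fr <- computeFractions(X, rspec)
  inten <- computeIntensities(expr, rspec, clipQuantile)

  # total normalized expression per cell (true scale, nTotal / n_list)
  sizes <- rep(lengths(rspec@genes), lengths(rspec@genes))
  totals <- as.vector(X %*% (nTotalGenes(rspec) / sizes))
  isEmpty <- totals == 0

  ext <- apply(coords, 2, function(v) diff(range(v)))
  if (is.null(rMax)) {
    rMax <- 0.015 * max(ext)
    if (rMax <= 0) rMax <- 1
  }
  if (is.null(rMin)) rMin <- rMax / 4
  if (!(rMax > rMin && rMin > 0))
    stopf("must have rMax > rMin > 0")

  pos <- totals[!isEmpty]
  totalMax <- if (length(pos)) quantile(pos, clipQuantile, names = FALSE) else 1
  radii <- computeRadius(totals, totalMax, rMin, rMax)
  radii[isEmpty] <- rMin / 2

  methods::new("CellCompositionSet",
               cellIds = colnames(sce), genes = genes, groups = groups,
               fractions = unname(fr), intensities = unname(inten),
               radii = radii, isEmpty = isEmpty,
               coords = unname(as.matrix(coords)))
}
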