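#' @import methods
#' @importFrom stats quantile setNames
#' @importFrom utils head read.csv read.delim write.csv
NULL

#' Ordered gene lists with color rules
#'
#' A \code{GeneListSpec} holds one or more ordered, disjoint groups of marker
#' genes, each paired with a color rule (a single color such as
#' \code{"#FF0000"} or \code{"blue"}, or the name of a colormap in
#' \code{\link{paletteRegistry}}). Group order and within-group gene order are
#' meaningful: they determine slice order in the glyphs and color positions on
#' a colormap.
#'
#' The group sizes drive the list-size normalization: for a gene in a group of
#' size \eqn{N_{list}} out of \eqn{N_{total}} genes overall, expression is
#' rescaled by \eqn{N_{total}/N_{list}} so that lists of unequal length
#' receive equal total weight (see \code{\link{normalizeExpression}}).
#'
#' @slot groupNames character vector of unique group names.
#' @slot genes list of character vectors, one per group, each non-empty;
#'   no gene may appear twice (within or across groups).
#' @slot colorRules character vector, one rule per group.
#'
#' @aliases GeneListSpec-class
#' @seealso \code{\link{readGeneLists}}, \code{\link{assignColors}}
#' @export GeneListSpec
#' @exportClass GeneListSpec
#'
#' @examples
#' GeneListSpec(
#'   genes = list(M1 = c("CD80", "CD86"), M2 = c("MRC1", "CD163")),
#'   colorRules = c("autumn", "winter")
#' )
GeneListSpec <- setClass(
  "GeneListSpec",
  slots = c(groupNames = "character", genes = "list", colorRules = "character")
)

setValidity("GeneListSpec", function(object) {
  msgs <- character()
  ng <- length(object@groupNames)
  if (length(object@genes) != ng || length(object@colorRules) != ng)
    msgs <- c(msgs, "groupNames, genes and colorRules must have one entry per group")
  if (anyDuplicated(object@groupNames))
    msgs <- c(msgs, "group names must be unique")
  if (ng > 0 && any(!nzchar(object@groupNames)))
    msgs <- c(msgs, "group names must be non-empty strings")
  for (i in seq_len(ng)) {
    g <- object@genes[[i]]
    if (!is.character(g) || length(g) == 0L || any(is.na(g)) || any(!nzchar(g))) {
      msgs <- c(msgs, sprintf("group '%s' must be a non-empty character vector",
                              object@groupNames[i]))
    }
  }
  allg <- unlist(object@genes, use.names = FALSE)
  dup <- unique(allg[duplicated(allg)])
  if (length(dup))
    msgs <- c(msgs, sprintf("gene(s) present in more than one list (or repeated): %s",
                            paste(dup, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @param genes list of character vectors (one per group). Names are used as
#'   group names unless \code{groupNames} is given.
#' @param colorRules character vector of color rules, one per group.
#' @param groupNames optional character vector of group names.
#' @rdname GeneListSpec-class
setMethod("initialize", "GeneListSpec", function(.Object, genes = list(),
                                                 colorRules = character(),
                                                 groupNames = NULL, ...) {
  if (is.null(groupNames)) {
    groupNames <- if (!is.null(names(genes))) names(genes)
                  else if (length(genes)) paste0("group", seq_along(genes))
                  else character()
  }
  genes <- unname(lapply(genes, as.character))
  callNextMethod(.Object, genes = genes, colorRules = as.character(colorRules),
                 groupNames = as.character(groupNames), ...)
})

#' Base colors assigned to genes
#'
#' Maps every gene of a \code{\link{GeneListSpec}} to one base RGB color,
#' either a group-wide single color or a colormap sample at position
#' \eqn{i/(n-1)} for the \eqn{i}-th of \eqn{n} genes (0-based, list order).
#'
#' @slot genes character vector of gene names in concatenated list order.
#' @slot colors numeric matrix (genes x 3), RGB channels in [0, 1], rownames
#'   are the gene names.
#' @slot rules data.frame with columns \code{group}, \code{rule} and
#'   \code{type} (\code{"color"} or \code{"colormap"}) recording how each
#'   group was colored.
#'
#' @aliases ColorAssignment-class
#' @seealso \code{\link{assignColors}}, \code{\link{applyIntensity}}
#' @exportClass ColorAssignment
setClass(
  "ColorAssignment",
  slots = c(genes = "character", colors = "matrix", rules = "data.frame")
)

setValidity("ColorAssignment", function(object) {
  msgs <- character()
  if (nrow(object@colors) != length(object@genes))
    msgs <- c(msgs, "one color row per gene required")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "genes must be unique")
  if (length(object@colors) && (ncol(object@colors) != 3L ||
      any(object@colors < 0) || any(object@colors > 1)))
    msgs <- c(msgs, "colors must be an RGB matrix with channels in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Per-cell slice fractions, intensities and glyph radii
#'
#' The numeric core of a pie-glyph plot: for each cell (or cluster, in
#' aggregated mode) the fraction of each gene's normalized expression, the
#' per-gene color intensity, the glyph radius in embedding units and the 2-D
#' glyph center. Cells whose selected genes are all zero are flagged
#' \code{isEmpty}; their fractions are all zero and they are drawn as small
#' neutral dots.
#'
#' @slot cellIds character vector of cell identifiers.
#' @slot genes character vector of gene names in concatenated list order.
#' @slot groups character vector parallel to \code{genes} giving each gene's
#'   group name.
#' @slot fractions numeric matrix (cells x genes); rows of non-empty cells sum
#'   to 1 within 1e-9, rows of empty cells are all zero.
#' @slot intensities numeric matrix (cells x genes) in [0, 1].
#' @slot radii numeric vector of glyph radii (> 0, embedding units).
#' @slot isEmpty logical vector flagging zero-expression cells.
#' @slot coords numeric matrix (cells x 2) of glyph centers.
#'
#' @aliases CellCompositionSet-class
#' @seealso \code{\link{buildCellCompositions}}, \code{\link{layoutGlyphs}},
#'   \code{\link{writeCompositionTable}}
#' @exportClass CellCompositionSet
setClass(
  "CellCompositionSet",
  slots = c(cellIds = "character", genes = "character", groups = "character",
            fractions = "matrix", intensities = "matrix", radii = "numeric",
            isEmpty = "logical", coords = "matrix")
)

setValidity("CellCompositionSet", function(object) {
  msgs <- character()
  n <- length(object@cellIds)
  p <- length(object@genes)
  if (length(object@groups) != p)
    msgs <- c(msgs, "groups must parallel genes")
  for (nm in c("fractions", "intensities")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, p)))
      msgs <- c(msgs, sprintf("%s must be a cells x genes matrix", nm))
  }
  if (length(object@radii) != n || length(object@isEmpty) != n)
    msgs <- c(msgs, "radii and isEmpty must have one entry per cell")
  if (n > 0 && (nrow(object@coords) != n || ncol(object@coords) != 2L))
    msgs <- c(msgs, "coords must be a cells x 2 matrix")
  if (any(object@radii <= 0))
    msgs <- c(msgs, "all radii must be positive")
  if (n > 0 && p > 0) {
    if (any(object@fractions < 0) || any(object@fractions > 1 + 1e-12))
      msgs <- c(msgs, "fractions must lie in [0, 1]")
    rs <- rowSums(object@fractions)
    if (any(abs(rs[!object@isEmpty] - 1) > 1e-9))
      msgs <- c(msgs, "fractions of non-empty cells must sum to 1 within 1e-9")
    if (any(rs[object@isEmpty] != 0))
      msgs <- c(msgs, "fractions of empty cells must all be zero")
    if (any(object@intensities < 0) || any(object@intensities > 1))
      msgs <- c(msgs, "intensities must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Geometry of one pie glyph
#'
#' A laid-out glyph: a center and radius in embedding units plus an ordered
#' set of wedges. Angles are in degrees, measured clockwise from 12 o'clock;
#' wedge \eqn{i} spans \eqn{360 \cdot fraction_i} degrees. Non-empty glyphs
#' tile the full circle (arc sum 360 within 1e-6); empty cells carry no
#' wedges and are drawn as a neutral dot.
#'
#' @slot cellId character cell identifier.
#' @slot center numeric length-2 center (embedding units).
#' @slot radius positive glyph radius (embedding units).
#' @slot wedges data.frame with columns \code{gene}, \code{start}, \code{end}
#'   (degrees) and \code{fill} (hex color); zero rows for empty cells.
#' @slot isEmpty logical flag.
#'
#' @aliases PieGlyph-class
#' @seealso \code{\link{layoutGlyph}}, \code{\link{renderFigure}}
#' @exportClass PieGlyph
setClass(
  "PieGlyph",
  slots = c(cellId = "character", center = "numeric", radius = "numeric",
            wedges = "data.frame", isEmpty = "logical")
)

setValidity("PieGlyph", function(object) {
  msgs <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msgs <- c(msgs, "center must be two finite coordinates")
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    msgs <- c(msgs, "radius must be a single positive number")
  w <- object@wedges
  if (!all(c("gene", "start", "end", "fill") %in% names(w)))
    msgs <- c(msgs, "wedges need columns gene, start, end, fill")
  if (!object@isEmpty) {
    if (nrow(w) == 0L) {
      msgs <- c(msgs, "non-empty glyph must have at least one wedge")
    } else {
      arcs <- w$end - w$start
      if (any(arcs <= 0))
        msgs <- c(msgs, "wedge arcs must be positive")
      if (abs(sum(arcs) - 360) > 1e-6)
        msgs <- c(msgs, "wedge arcs must sum to 360 degrees within 1e-6")
    }
  } else if (nrow(w) != 0L) {
    msgs <- c(msgs, "empty glyph must have no wedges")
  }
  if (length(msgs)) msgs else TRUE
})

#' Rendering parameters
#'
#' Canvas and glyph-scaling parameters shared by the cell and cluster plot
#' modes. \code{rMin}/\code{rMax} are in embedding units; when \code{NA} they
#' are derived from the embedding extent at layout time (\code{rMax} defaults
#' to 1.5\% of the larger extent, \code{rMin} to \code{rMax/4}).
#'
#' @slot width,height canvas size in pixels.
#' @slot rMin,rMax glyph radius bounds in embedding units (\code{NA} = auto).
#' @slot clipQuantile quantile in (0, 1] used to clip per-gene intensities and
#'   per-cell totals (robustness against outliers).
#' @slot lightenColors logical; interpolate slice colors toward white as
#'   intensity decreases.
#' @slot emptyColor hex color of the dot drawn for zero-expression cells.
#' @slot format output format, \code{"svg"} or \code{"png"}.
#' @slot dpi raster resolution for PNG output.
#' @slot legendFraction fraction of canvas width reserved for the legend.
#'
#' @aliases RenderConfig-class
#' @seealso \code{\link{renderConfig}}, \code{\link{renderFigure}}
#' @exportClass RenderConfig
setClass(
  "RenderConfig",
  slots = c(width = "numeric", height = "numeric", rMin = "numeric",
            rMax = "numeric", clipQuantile = "numeric",
            lightenColors = "logical", emptyColor = "character",
            format = "character", dpi = "numeric", legendFraction = "numeric")
)

setValidity("RenderConfig", function(object) {
  msgs <- character()
  if (object@width <= 0 || object@height <= 0)
    msgs <- c(msgs, "canvas width and height must be positive")
  if (!is.na(object@rMin) && !is.na(object@rMax) &&
      !(object@rMax > object@rMin && object@rMin > 0))
    msgs <- c(msgs, "must have rMax > rMin > 0")
  if (!(object@clipQuantile > 0 && object@clipQuantile <= 1))
    msgs <- c(msgs, "clipQuantile must lie in (0, 1]")
  if (!object@format %in% c("svg", "png"))
    msgs <- c(msgs, "format must be 'svg' or 'png'")
  if (object@dpi <= 0)
    msgs <- c(msgs, "dpi must be positive")
  if (object@legendFraction < 0 || object@legendFraction >= 1)
    msgs <- c(msgs, "legendFraction must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Per-cluster expression summaries ("big pies")
#'
#' One summary per cell cluster: the number of member cells, the centroid of
#' the member cells' embedding coordinates, the arithmetic mean expression of
#' the selected genes, and the composition of that mean vector. Summaries are
#' ordered by decreasing cell count (ties broken by label).
#'
#' @slot labels character cluster labels.
#' @slot nCells integer member counts (>= 1).
#' @slot centroids numeric matrix (clusters x 2).
#' @slot meanExpression numeric matrix (clusters x genes), per-gene arithmetic
#'   means over member cells.
#' @slot composition a \code{\link{CellCompositionSet}} with one row per
#'   cluster (fractions of the mean vector; intensities on the same per-gene
#'   clip scale as the cell-level plot; radii from \code{\link{clusterRadii}}).
#'
#' @aliases ClusterSummarySet-class
#' @seealso \code{\link{summarizeClusters}}, \code{\link{clusterRadii}}
#' @exportClass ClusterSummarySet
setClass(
  "ClusterSummarySet",
  slots = c(labels = "character", nCells = "integer", centroids = "matrix",
            meanExpression = "matrix", composition = "CellCompositionSet")
)

setValidity("ClusterSummarySet", function(object) {
  msgs <- character()
  k <- length(object@labels)
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "cluster labels must be unique")
  if (length(object@nCells) != k || any(object@nCells < 1L))
    msgs <- c(msgs, "every cluster must have at least one member cell")
  if (k > 0 && (nrow(object@centroids) != k || ncol(object@centroids) != 2L))
    msgs <- c(msgs, "centroids must be a clusters x 2 matrix")
  if (k > 0 && nrow(object@meanExpression) != k)
    msgs <- c(msgs, "meanExpression must have one row per cluster")
  if (any(object@meanExpression < 0))
    msgs <- c(msgs, "mean expression must be non-negative")
  if (length(object@composition@cellIds) != k)
    msgs <- c(msgs, "composition must have one entry per cluster")
  if (length(msgs)) msgs else TRUE
})
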