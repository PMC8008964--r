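# Accessor and show methods.

#' @rdname scPies-accessors
#' @export
setMethod("groupNames", "GeneListSpec", function(x) x@groupNames)

#' @rdname scPies-accessors
#' @export
setMethod("groupGenes", "GeneListSpec", function(x) setNames(x@genes, x@groupNames))

#' @rdname scPies-accessors
#' @export
setMethod("colorRules", "GeneListSpec", function(x) setNames(x@colorRules, x@groupNames))

#' @rdname scPies-accessors
#' @export
setMethod("groupSizes", "GeneListSpec",
          function(x) setNames(lengths(x@genes), x@groupNames))

#' @rdname scPies-accessors
#' @export
setMethod("nTotalGenes", "GeneListSpec", function(x) sum(lengths(x@genes)))

setMethod("show", "GeneListSpec", function(object) {
  cat(sprintf("GeneListSpec with %d group(s), %d gene(s) total\n",
              length(object@groupNames), nTotalGenes(object)))
  for (i in seq_along(object@groupNames)) {
    g <- object@genes[[i]]
    cat(sprintf("  %s [%s]: %s%s\n", object@groupNames[i], object@colorRules[i],
                paste(head(g, 6), collapse = ", "),
                if (length(g) > 6) sprintf(", ... (%d genes)", length(g)) else ""))
  }
})

# internal: long-format gene table (gene, group, group size)
geneTable <- function(spec) {
  data.frame(
    gene = unlist(spec@genes, use.names = FALSE),
    group = rep(spec@groupNames, lengths(spec@genes)),
    group_size = rep(lengths(spec@genes), lengths(spec@genes)),
    stringsAsFactors = FALSE
  )
}

#' @rdname scPies-accessors
#' @export
setMethod("cellIds", "CellCompositionSet", function(x) x@cellIds)

#' @rdname scPies-accessors
#' @export
setMethod("fractions", "CellCompositionSet", function(x) x@fractions)

#' @rdname scPies-accessors
#' @export
setMethod("intensities", "CellCompositionSet", function(x) x@intensities)

#' @rdname scPies-accessors
#' @export
setMethod("glyphRadii", "CellCompositionSet", function(x) x@radii)

#' @rdname scPies-accessors
#' @export
setMethod("isEmptyCell", "CellCompositionSet", function(x) x@isEmpty)

#' @rdname scPies-accessors
#' @export
setMethod("glyphCenters", "CellCompositionSet", function(x) x@coords)

#' @rdname scPies-accessors
#' @export
setMethod("compositionGenes", "CellCompositionSet", function(x) x@genes)

#' @rdname scPies-accessors
#' @export
setMethod("compositionGroups", "CellCompositionSet",
          function(x) setNames(x@groups, x@genes))

setMethod("show", "CellCompositionSet", function(object) {
  cat(sprintf("CellCompositionSet: %d cell(s) x %d gene(s), %d empty cell(s)\n",
              length(object@cellIds), length(object@genes), sum(object@isEmpty)))
  if (length(object@genes))
    cat("  genes:", paste(head(object@genes, 8), collapse = ", "),
        if (length(object@genes) > 8) "..." else "", "\n")
})

#' Long-format composition table
#'
#' Flattens a \code{\link{CellCompositionSet}} to one row per (cell, gene)
#' with columns \code{cell_id}, \code{gene}, \code{group}, \code{fraction},
#' \code{intensity}, \code{radius}.
#'
#' @param x a \code{CellCompositionSet}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a data.frame in cell-major order.
#' @export
as.data.frame.CellCompositionSet <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  n <- length(x@cellIds)
  p <- length(x@genes)
  data.frame(
    cell_id = rep(x@cellIds, each = p),
    gene = rep(x@genes, times = n),
    group = rep(x@groups, times = n),
    fraction = as.vector(t(x@fractions)),
    intensity = as.vector(t(x@intensities)),
    radius = rep(x@radii, each = p),
    stringsAsFactors = FALSE
  )
}

#' @rdname scPies-accessors
#' @export
setMethod("baseColors", "ColorAssignment", function(x) {
  m <- x@colors
  rownames(m) <- x@genes
  m
})

#' @rdname scPies-accessors
#' @export
setMethod("colorRuleTable", "ColorAssignment", function(x) x@rules)

setMethod("show", "ColorAssignment", function(object) {
  cat(sprintf("ColorAssignment for %d gene(s)\n", length(object@genes)))
  for (i in seq_len(nrow(object@rules)))
    cat(sprintf("  %s: %s (%s)\n", object@rules$group[i], object@rules$rule[i],
                object@rules$type[i]))
})

#' @rdname scPies-accessors
#' @export
setMethod("wedges", "PieGlyph", function(x) x@wedges)

#' @rdname scPies-accessors
#' @export
setMethod("glyphCenters", "PieGlyph", function(x) x@center)

#' @rdname scPies-accessors
#' @export
setMethod("glyphRadii", "PieGlyph", function(x) x@radius)

#' @rdname scPies-accessors
#' @export
setMethod("isEmptyCell", "PieGlyph", function(x) x@isEmpty)

setMethod("show", "PieGlyph", function(object) {
  cat(sprintf("PieGlyph '%s' at (%.3g, %.3g), radius %.3g, %d wedge(s)%s\n",
              object@cellId, object@center[1], object@center[2], object@radius,
              nrow(object@wedges), if (object@isEmpty) " [empty]" else ""))
})

#' @rdname scPies-accessors
#' @export
setMethod("clusterLabels", "ClusterSummarySet", function(x) x@labels)

#' @rdname scPies-accessors
#' @export
setMethod("clusterSizes", "ClusterSummarySet",
          function(x) setNames(x@nCells, x@labels))

#' @rdname scPies-accessors
#' @export
setMethod("clusterCentroids", "ClusterSummarySet", function(x) {
  m <- x@centroids
  rownames(m) <- x@labels
  m
})

#' @rdname scPies-accessors
#' @export
setMethod("meanExpression", "ClusterSummarySet", function(x) {
  m <- x@meanExpression
  rownames(m) <- x@labels
  m
})

#' @rdname scPies-accessors
#' @export
setMethod("clusterComposition", "ClusterSummarySet", function(x) x@composition)

setMethod("show", "ClusterSummarySet", function(object) {
  cat(sprintf("ClusterSummarySet with %d cluster(s)\n", length(object@labels)))
  for (i in seq_along(object@labels))
    cat(sprintf("  %s: %d cells, centroid (%.3g, %.3g)\n", object@labels[i],
                object@nCells[i], object@centroids[i, 1], object@centroids[i, 2]))
})
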