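#' Accessors for scPies classes
#'
#' Small accessor generics; prefer these over direct slot access.
#'
#' @param x an scPies object (\code{\link{GeneListSpec}},
#'   \code{\link{CellCompositionSet}}, \code{\link{ColorAssignment}},
#'   \code{\link{PieGlyph}} or \code{\link{ClusterSummarySet}}).
#' @return The corresponding component (see each method's class documentation).
#' @name scPies-accessors
#' @rdname scPies-accessors
#' @examples
#' spec <- GeneListSpec(list(a = c("G1", "G2"), b = "G3"), c("blue", "red"))
#' groupNames(spec)
#' groupSizes(spec)
#' nTotalGenes(spec)
NULL

#' @rdname scPies-accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))
#' @rdname scPies-accessors
#' @export
setGeneric("groupGenes", function(x) standardGeneric("groupGenes"))
#' @rdname scPies-accessors
#' @export
setGeneric("colorRules", function(x) standardGeneric("colorRules"))
#' @rdname scPies-accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))
#' @rdname scPies-accessors
#' @export
setGeneric("nTotalGenes", function(x) standardGeneric("nTotalGenes"))

#' @rdname scPies-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname scPies-accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname scPies-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname scPies-accessors
#' @export
setGeneric("glyphRadii", function(x) standardGeneric("glyphRadii"))
#' @rdname scPies-accessors
#' @export
setGeneric("isEmptyCell", function(x) standardGeneric("isEmptyCell"))
#' @rdname scPies-accessors
#' @export
setGeneric("glyphCenters", function(x) standardGeneric("glyphCenters"))
#' @rdname scPies-accessors
#' @export
setGeneric("compositionGenes", function(x) standardGeneric("compositionGenes"))
#' @rdname scPies-accessors
#' @export
setGeneric("compositionGroups", function(x) standardGeneric("compositionGroups"))

#' @rdname scPies-accessors
#' @export
setGeneric("baseColors", function(x) standardGeneric("baseColors"))
#' @rdname scPies-accessors
#' @export
setGeneric("colorRuleTable", function(x) standardGeneric("colorRuleTable"))

#' @rdname scPies-accessors
#' @export
setGeneric("wedges", function(x) standardGeneric("wedges"))

#' @rdname scPies-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname scPies-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @rdname scPies-accessors
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @rdname scPies-accessors
#' @export
setGeneric("meanExpression", function(x) standardGeneric("meanExpression"))
#' @rdname scPies-accessors
#' @export
setGeneric("clusterComposition", function(x) standardGeneric("clusterComposition"))
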