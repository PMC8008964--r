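# End-to-end pipeline used by the command-line interface.

#' Default pipeline configuration
#'
#' Returns the default run configuration as a named list; \code{runPipeline}
#' merges user settings over these defaults. Fields mirror the command-line
#' flags (see the \code{scpies} script in \code{inst/scripts}).
#'
#' @return a named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    expression = NULL,
    format = "auto",             # auto | csv | tsv | mtx
    orientation = "genes-rows",  # genes-rows | cells-rows
    coords = NULL,
    geneLists = character(),
    colors = character(),
    clusters = NULL,
    mode = "cells",              # cells | clusters
    lightenColors = TRUE,
    clipQuantile = 0.99,
    rMin = NULL,
    rMax = NULL,
    width = 900,
    height = 700,
    dpi = 150,
    out = NULL,
    outFormat = "svg",
    compositionOut = NULL,
    caseInsensitive = FALSE,
    missingGenePolicy = "drop-warn"  # drop-warn | error
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file whose keys mirror the command-line flags
#' (\code{expression}, \code{coords}, \code{gene-list}, \code{color},
#' \code{clusters}, \code{mode}, \code{lighten-colors}, \code{clip-quantile},
#' \code{r-min}, \code{r-max}, \code{out}, \code{out-format},
#' \code{composition-out}, \code{case-insensitive},
#' \code{missing-gene-policy}, ...). Flags given on the command line override
#' file values.
#'
#' @param path YAML file path.
#' @return a configuration list in \code{\link{runPipeline}} form.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  ren <- c("gene-list" = "geneLists", "color" = "colors",
           "lighten-colors" = "lightenColors", "clip-quantile" = "clipQuantile",
           "r-min" = "rMin", "r-max" = "rMax", "out-format" = "outFormat",
           "composition-out" = "compositionOut",
           "case-insensitive" = "caseInsensitive",
           "missing-gene-policy" = "missingGenePolicy")
  names(y) <- ifelse(names(y) %in% names(ren), ren[names(y)], names(y))
  for (f in c("geneLists", "colors"))
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  y
}

#' Run the full plotting pipeline
#'
#' Executes read, align, resolve, compose, color and render for the cell mode
#' (one pie glyph per cell) or the cluster mode (one big pie per cluster,
#' sized by cell count), writing the figure, the auto-generated legend and,
#' optionally, the composition table.
#'
#' @param config a named list; missing fields are filled from
#'   \code{\link{defaultRunConfig}}. Required: \code{expression},
#'   \code{coords}, \code{geneLists}, \code{colors}, \code{out};
#'   \code{mode = "clusters"} additionally requires \code{clusters}.
#' @return invisibly, a list with the aligned experiment, the resolved
#'   composition (or cluster summaries), the color assignment, the legend and
#'   the output paths.
#' @export
#' @examples
#' fix <- simulateCells(seed = 7)
#' dir <- tempfile(); writeFixture(fix, dir)
#' cfg <- readRunConfig(file.path(dir, "config.yaml"))
#' cfg$out <- file.path(dir, "cells.svg")
#' res <- runPipeline(cfg)
#' file.exists(cfg$out)
runPipeline <- function(config = list()) {
  cfg <- defaultRunConfig()
  cfg[names(config)] <- config

  for (f in c("expression", "coords", "out"))
    if (is.null(cfg[[f]]))
      stopf("missing required setting '--%s'", f)
  if (length(cfg$geneLists) == 0)
    stopf("at least one '--gene-list' is required")
  if (length(cfg$colors) != length(cfg$geneLists))
    stopf("need one '--color' per '--gene-list' (%d lists, %d colors)",
          length(cfg$geneLists), length(cfg$colors))
  cfg$mode <- match.arg(cfg$mode, c("cells", "clusters"))
  if (cfg$mode == "clusters" && is.null(cfg$clusters))
    stopf("mode 'clusters' requires '--clusters' (a cell/cluster assignment file)")

  format <- switch(cfg$format, auto = "auto", csv = "delimited",
                   tsv = "delimited", mtx = "matrixmarket",
                   stopf("unknown expression format '%s'", cfg$format))
  orientation <- switch(cfg$orientation,
                        `genes-rows` = "genes_as_rows",
                        `cells-rows` = "cells_as_rows",
                        stopf("unknown orientation '%s'", cfg$orientation))
  policy <- switch(cfg$missingGenePolicy,
                   `drop-warn` = "drop_warn", drop_warn = "drop_warn",
                   error = "error",
                   stopf("unknown missing-gene policy '%s'", cfg$missingGenePolicy))

  sce <- readExpressionMatrix(cfg$expression, orientation = orientation,
                              format = format)
  coords <- readCoordinates(cfg$coords)
  spec <- readGeneLists(cfg$geneLists, cfg$colors)
  clusters <- if (!is.null(cfg$clusters)) readClusterAssignments(cfg$clusters)
  sce <- alignCells(sce, coords, clusters = clusters)

  rconf <- renderConfig(width = cfg$width, height = cfg$height,
                        rMin = if (is.null(cfg$rMin)) NA_real_ else cfg$rMin,
                        rMax = if (is.null(cfg$rMax)) NA_real_ else cfg$rMax,
                        clipQuantile = cfg$clipQuantile,
                        lightenColors = cfg$lightenColors,
                        format = cfg$outFormat, dpi = cfg$dpi)

  if (cfg$mode == "cells") {
    comp <- buildCellCompositions(sce, spec, clipQuantile = cfg$clipQuantile,
                                  rMin = cfg$rMin, rMax = cfg$rMax,
                                  missingGenePolicy = policy,
                                  caseInsensitive = cfg$caseInsensitive)
    result <- comp
  } else {
    summaries <- summarizeClusters(sce, spec, clipQuantile = cfg$clipQuantile,
                                   rMin = if (is.null(cfg$rMin)) 0 else cfg$rMin,
                                   rMax = cfg$rMax,
                                   missingGenePolicy = policy,
                                   caseInsensitive = cfg$caseInsensitive)
    comp <- clusterComposition(summaries)
    result <- summaries
  }

  rspec <- suppressWarnings(resolveGenes(sce, spec, policy = policy,
                                         caseInsensitive = cfg$caseInsensitive))
  assignment <- assignColors(rspec)
  legend <- buildLegendEntries(assignment, rspec)
  glyphs <- layoutGlyphs(comp, assignment, rconf)
  renderFigure(glyphs, legend, rconf, cfg$out)
  message(sprintf("wrote %s (%d glyph%s)", cfg$out, length(glyphs),
                  if (length(glyphs) == 1) "" else "s"))

  if (!is.null(cfg$compositionOut)) {
    writeCompositionTable(comp, cfg$compositionOut)
    message(sprintf("wrote %s", cfg$compositionOut))
  }

  invisible(list(sce = sce, result = result, assignment = assignment,
                 legend = legend, figure = cfg$out,
                 compositionTable = cfg$compositionOut))
}
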