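# Gene color assignment: colormap sampling, single colors, intensity
# lightening and legend construction.

# two-anchor linear ramp in RGB
ramp2 <- function(from, to) {
  f <- grDevices::colorRamp(c(from, to), space = "rgb")
  function(t) f(t) / 255
}

hclRamp <- function(palette) {
  f <- grDevices::colorRamp(grDevices::hcl.colors(256, palette), space = "rgb")
  function(t) f(t) / 255
}

#' Registry of named colormaps
#'
#' Returns the built-in colormaps available as group color rules. Each entry
#' is a function mapping positions in [0, 1] to an RGB matrix (channels in
#' [0, 1]). The registry contains the classic two-anchor ramps
#' (\code{winter}: blue to green, \code{autumn}: red to yellow,
#' \code{spring}, \code{summer}, \code{cool}, \code{gray}) and
#' perceptually-ordered multi-hue maps sampled from
#' \code{\link[grDevices]{hcl.colors}} (\code{viridis}, \code{plasma},
#' \code{inferno}, \code{mako}, \code{rocket}, \code{heat}, \code{blues},
#' \code{greens}, \code{purples}, \code{reds}).
#'
#' @return a named list of vectorized colormap functions.
#' @seealso \code{\link{assignColors}}
#' @export
#' @examples
#' reg <- paletteRegistry()
#' names(reg)
#' reg$gray(c(0, 0.5, 1))
paletteRegistry <- function() {
  list(
    winter = ramp2(grDevices::rgb(0, 0, 1), grDevices::rgb(0, 1, 0.5)),
    autumn = ramp2(grDevices::rgb(1, 0, 0), grDevices::rgb(1, 1, 0)),
    spring = ramp2(grDevices::rgb(1, 0, 1), grDevices::rgb(1, 1, 0)),
    summer = ramp2(grDevices::rgb(0, 0.5, 0.4), grDevices::rgb(1, 1, 0.4)),
    cool   = ramp2(grDevices::rgb(0, 1, 1), grDevices::rgb(1, 0, 1)),
    gray   = ramp2("black", "white"),
    viridis = hclRamp("Viridis"),
    plasma  = hclRamp("Plasma"),
    inferno = hclRamp("Inferno"),
    mako    = hclRamp("Mako"),
    rocket  = hclRamp("Rocket"),
    heat    = hclRamp("Heat"),
    blues   = hclRamp("Blues 3"),
    greens  = hclRamp("Greens 3"),
    purples = hclRamp("Purples 3"),
    reds    = hclRamp("Reds 3")
  )
}

# parse "#RRGGBB" or an R color name into an RGB triple in [0,1]
parseColor <- function(s) {
  if (grepl("^#[0-9a-fA-F]{6}$", s))
    return(as.vector(grDevices::col2rgb(s)) / 255)
  if (tolower(s) %in% grDevices::colors())
    return(as.vector(grDevices::col2rgb(tolower(s))) / 255)
  stopf("color rule '%s' is neither a known colormap nor a valid color (use a registry name, '#RRGGBB', or an R color name)",
        s)
}

#' Assign a base color to every gene
#'
#' For a group whose rule names a colormap, the \eqn{i}-th of \eqn{n} genes
#' (0-based, list order) gets the colormap value at position \eqn{i/(n-1)}
#' (a single gene samples position 0), spanning the full map so colors are
#' maximally distinguishable. For a single-color rule every gene in the group
#' gets that color. The assignment is deterministic.
#'
#' @param spec a (resolved) \code{\link{GeneListSpec}}.
#' @param registry colormap registry, by default \code{\link{paletteRegistry}}.
#' @return a \code{\link{ColorAssignment}}.
#' @export
#' @examples
#' spec <- GeneListSpec(list(g = c("A", "B", "C")), "gray")
#' baseColors(assignColors(spec))  # positions 0, 0.5, 1
assignColors <- function(spec, registry = paletteRegistry()) {
  genes <- character()
  cols <- matrix(numeric(), ncol = 3)
  rules <- data.frame(group = character(), rule = character(),
                      type = character(), stringsAsFactors = FALSE)
  for (i in seq_along(spec@groupNames)) {
    g <- spec@genes[[i]]
    rule <- spec@colorRules[i]
    if (tolower(rule) %in% names(registry)) {
      n <- length(g)
      t <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
      m <- registry[[tolower(rule)]](t)
      type <- "colormap"
    } else {
      m <- matrix(parseColor(rule), nrow = length(g), ncol = 3, byrow = TRUE)
      type <- "color"
    }
    genes <- c(genes, g)
    cols <- rbind(cols, m)
    rules <- rbind(rules, data.frame(group = spec@groupNames[i], rule = rule,
                                     type = type, stringsAsFactors = FALSE))
  }
  cols <- pmin(pmax(cols, 0), 1)
  methods::new("ColorAssignment", genes = genes, colors = unname(cols),
               rules = rules)
}

#' Modulate a color by expression intensity
#'
#' Interpolates a base color toward white in proportion to
#' \code{1 - intensity}: full intensity returns the base color, zero intensity
#' returns white, per channel
#' \code{white + intensity * (base - white)}. With lightening disabled the
#' base color is returned unchanged (all slices fully saturated).
#'
#' @param base an RGB triple in [0, 1], or an n x 3 matrix of them.
#' @param intensity value(s) in [0, 1] (scalar or one per row of \code{base}).
#' @param lightenEnabled logical, default \code{TRUE}.
#' @return RGB triple(s), same shape as \code{base}.
#' @export
#' @examples
#' applyIntensity(c(0, 0, 1), 0.5)  # 0.5 0.5 1
applyIntensity <- function(base, intensity, lightenEnabled = TRUE) {
  if (any(is.na(intensity)) || any(intensity < 0) || any(intensity > 1))
    stopf("intensity must lie in [0, 1]")
  m <- rbind(base)
  if (any(m < 0) || any(m > 1))
    stopf("base color channels must lie in [0, 1]")
  if (!lightenEnabled)
    return(base)
  out <- 1 - intensity * (1 - m)
  if (is.null(dim(base))) as.vector(out) else out
}

#' Legend entries for a color assignment
#'
#' One entry per gene in concatenated list order, grouped under a header row
#' per group, ready for \code{\link{renderFigure}}.
#'
#' @param assignment a \code{\link{ColorAssignment}}.
#' @param spec the matching \code{\link{GeneListSpec}}.
#' @return a data.frame with columns \code{label}, \code{color} (hex;
#'   \code{NA} on header rows) and \code{is_header}.
#' @export
buildLegendEntries <- function(assignment, spec) {
  out <- data.frame(label = character(), color = character(),
                    is_header = logical(), stringsAsFactors = FALSE)
  cols <- baseColors(assignment)
  for (i in seq_along(spec@groupNames)) {
    g <- spec@genes[[i]]
    out <- rbind(out,
                 data.frame(label = spec@groupNames[i], color = NA_character_,
                            is_header = TRUE, stringsAsFactors = FALSE),
                 data.frame(label = g, color = hexFromRgb(cols[g, , drop = FALSE]),
                            is_header = FALSE, stringsAsFactors = FALSE))
  }
  out
}
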