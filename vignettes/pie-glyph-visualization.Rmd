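---
title: "Pie-glyph visualization of single-cell embeddings: methods and design"
author: "scPies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pie-glyph visualization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scPies)
```

## The visualization model

scPies renders each cell of a 2-D single-cell embedding (UMAP, t-SNE, or
any coordinate export) as a pie-chart glyph. The inputs are a non-negative
cell × gene expression matrix, per-cell coordinates, and one or more ordered
marker-gene lists, each with a color rule. For each cell the glyph encodes
three quantities:

1. **Slice angle** — gene *i*'s share of the cell's normalized expression,
   $f_i = X_{norm,i} / \sum_j X_{norm,j}$ with
   $X_{norm} = X \cdot N_{total} / N_{list}$, where $N_{total}$ is the
   number of genes across all lists and $N_{list}$ the size of the gene's
   own list. Wedges start at 12 o'clock and proceed clockwise in list
   order; wedge *i* spans $360 \cdot f_i$ degrees.
2. **Slice color intensity** — per-gene expression scaled to $[0,1]$
   against a robust per-gene reference (below) and, when lightening is
   enabled, interpolated from the gene's base color toward white as
   intensity falls.
3. **Glyph size** — the cell's total normalized expression mapped to a
   radius between `rMin` and `rMax` with square-root scaling, so glyph
   *area* is proportional to total expression up to a cap.

The list-size normalization is the methodological core: it weighs gene
lists of unequal length equally. If every gene is expressed at a common
value, each of $g$ lists receives exactly $1/g$ of the pie, whatever the
list sizes — without the correction an 8-gene list would paint twice the
pie of a 4-gene list at identical per-gene expression. The package treats
expression values as given (raw counts, library-normalized, or log values
all work mechanically); because fractions are scale invariant, a global
rescaling of the matrix changes nothing, but a *nonlinear* transform (log)
changes the composition, so mixing conventions between runs is the user's
responsibility. No transform is applied internally.

### Assumptions

- Expression is non-negative and finite; negative entries are rejected at
  read time rather than silently clipped.
- Cell identifiers connect the matrix, the embedding and the cluster
  assignment; the embedding's file order is the canonical cell order, so
  rendering and tables are deterministic.
- Gene symbols match exactly (case-sensitive) by default; a
  case-insensitive option uppercases both sides and adopts the matrix's
  spelling. Silent case folding is off by default because it hides real
  mismatches (e.g. murine vs human symbol conventions).

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `clipQuantile` | 0.99 | — | Quantile of a gene's *positive* values used as its intensity reference, and of the positive per-cell totals used as the radius cap. One robustness knob for both encodings; 1.0 uses the maximum (no outlier resistance). |
| `rMin`, `rMax` | auto | embedding units | Glyph radius bounds. `rMax` defaults to 1.5% of the larger embedding extent (dense plots stay readable without collision avoidance), `rMin` to `rMax/4`. |
| `lightenColors` | `TRUE` | — | Interpolate slice colors toward white with falling intensity; disabled, every slice is drawn fully saturated and only angle and size carry information. |
| `emptyColor` | `#BFBFBF` | — | Fill of the neutral dot used for zero-expression cells. |
| `missingGenePolicy` | `drop_warn` | — | Genes absent from the matrix are dropped with a warning naming them (or are an error). List sizes used in the normalization always reflect the *resolved* lists. |
| `orientation` | genes as rows | — | On-disk orientation of delimited matrices; MatrixMarket triples from droplet pipelines are genes × cells. |

Degenerate inputs are handled explicitly rather than propagated: a cell
whose selected genes are all zero is flagged *empty* (all fractions zero)
and drawn as a neutral dot of radius `rMin/2` — dropping such cells would
distort the embedding's silhouette, and giving them a full-size uniform pie
would invent composition that is not there. A gene with no positive values
anywhere gets intensity 0 with a warning. A group that loses *all* its
genes during resolution is an error under either policy, never a silent
skip: with it, $N_{total}$ and the implied group weighting would change
meaning.

## Color assignment

A group's color rule is either a single color (hex `#RRGGBB` or an R color
name) applied to every gene, or the name of a colormap. For a colormap
group with $n$ genes, gene $i$ (0-based, list order) samples the map at
position $i/(n-1)$ (a single gene samples 0). Sampling spans the full map —
a centered subrange would be safer against pale endpoints but wastes
dynamic range; full span maximizes pairwise distinguishability and puts
list order on the map's perceptual axis (e.g. early markers dark violet,
late markers yellow on `viridis`). The registry contains the classic
two-anchor ramps (`winter`, `autumn`, `spring`, `summer`, `cool`, `gray`)
and multi-hue maps sampled from `grDevices::hcl.colors`.

Intensity lightening interpolates in plain RGB toward white,
$c' = 1 - I\,(1 - c)$ per channel. RGB is not perceptually uniform, but the
mapping is monotone per channel, has exact endpoints ($I{=}1$ gives the
base color, $I{=}0$ white), and is reproducible bit-exactly, which the
deterministic-output contract needs. Legends are generated automatically:
one swatch per gene under its group header, wrapped into columns of at most
40 entries in a right margin reserved as 20% of the canvas width.

## Cluster mode ("big pies")

`summarizeClusters()` aggregates to one pie per cluster: per-gene
*arithmetic mean* expression over member cells (the median would break the
exact equivalence between mean and summed composition that scale invariance
provides), the coordinate centroid as the glyph center, and the composition
of the mean vector as the slices. Radii scale with member count as
$r_k = r_{min} + (r_{max}-r_{min})\sqrt{n_k/n_{max}}$, so with
$r_{min}=0$ pie areas are exactly proportional to cell counts. Per-cluster
intensities are computed against the *cell-level* per-gene clip values, so
a cell plot and a cluster plot of the same data are color-comparable.
Overlapping big pies are not repelled; summaries are ordered by descending
size (ties by label) so overdraw is deterministic.

## Numerical choices

- **Fraction arithmetic.** Internally the per-gene weights are
  $w_i = x_i \cdot N_{total} \cdot (L / N_{list,i})$ with $L$ the least
  common multiple of the resolved list sizes. A common positive factor
  cancels in $w_i/\sum w_j$, so this is exactly the normalized-expression
  fraction — but because $L/N_{list,i}$ is an integer, integer-valued
  expression input yields exactly representable weights and each fraction
  is a single correctly-rounded division. Fractions of small integer
  inputs therefore agree *bit for bit* with an exact-rational evaluation,
  which the test suite checks against an independent integer-arithmetic
  oracle.
- **Tolerances.** Non-empty fraction vectors sum to 1 within $10^{-9}$
  (class validity) and wedge arcs to 360° within $10^{-6}$; in practice
  both hold to a few ulps. Summed quantities (a group's total fraction,
  area ratios) are asserted to $10^{-12}$, which admits only the rounding
  of the summation itself.
- **Ties.** "Largest slice" uses first-in-list-order as the tie break;
  composition tables print reals at 6 decimal places so repeated runs are
  byte-identical.
- **SVG as reference output.** The SVG writer emits a fixed-format document
  (3-decimal coordinates, no timestamps), so identical inputs give
  byte-identical files; full-circle wedges are emitted as `<circle>`
  elements since a single SVG arc cannot span 360°. PNG rendering goes
  through the standard `grDevices` raster device with wedges tessellated at
  ≤ 2° steps; PNG is a convenience output and is not byte-compared.

## The synthetic-data generator

`simulateCells()` provides the package's test bed: $K$ isotropic Gaussian
blobs (centers evenly spaced on a circle of radius 5, spread 0.5) and
negative-binomial counts in which each cluster's *program genes* have mean
10 inside their home cluster and 0.1 elsewhere — a 100-fold
program-to-background ratio — with dispersion (`size`) 2, a typical
scRNA-seq overdispersion. Defaults are 3 clusters × 100 cells with one
program gene each; all output is a deterministic function of `seed` and the
caller's RNG state is restored.

The generator emulates the features the method depends on — cluster
structure in the embedding, cluster-specific gene programs, non-negative
overdispersed counts with dropout — and deliberately *not* others: no
library-size variation between cells, no correlated gene–gene noise, no
batch effects, no mixed or transitional populations, and perfectly
separable blobs instead of continuous trajectories. Passing tests therefore
demonstrate that the numeric pipeline is correct and deterministic under
realistic count statistics, not that the visualization is legible on any
particular real dataset.

The end-to-end check on this fixture asks for each cell whether the largest
slice falls on the home cluster's program gene. Recovery is measured over
*non-empty* cells: an all-zero cell has no slices (it is drawn as a neutral
dot) and makes no composition claim, so it can neither hit nor miss; with
negative-binomial dropout at mean 10 and size 2, about 3% of cells are
empty by chance. The suite requires ≥ 95% recovery, and the acceptance
script reports the observed rate.

## Problem sizes

The test suite and acceptance script run on deliberately small inputs: the
fixture at its default 300 cells, a 500-cell / 5-cluster render smoke test,
property checks over hundreds of randomized small gene-list
configurations (≤ 5 genes for the exact-rational oracle, up to 90 genes for
the equal-weighting property), and 1000-case property sweeps for the
normalization identities. These sizes exercise every code path while
keeping a full run in the order of a minute; the pipeline itself is linear
in cells × selected genes and has been run at a few thousand cells without
issue. Rendering tens of thousands of per-cell glyphs produces large SVG
documents; PNG output is the practical choice at that scale.

## Known limitations

- No collision avoidance between glyphs; at very high cell densities pies
  overlap and the default `rMax` (1.5% of the extent) is a compromise, not
  an optimum.
- Slice angles below ~1° are not visually resolvable even though they are
  present in the SVG and the composition table.
- RGB-toward-white lightening compresses perceptual differences for
  already-light base colors; single-color groups on light colors benefit
  from disabling lightening.
- The composition is relative: a cell expressing one list weakly and
  nothing else shows a full pie of that list's color. The intensity and
  size encodings are the counterweight — interpreting a plot requires all
  three channels, which is why both are on by default.
- HDF5/loom/AnnData containers and proprietary single-cell serializations
  are out of scope; export to CSV/TSV/MatrixMarket first.
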