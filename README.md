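# scPies

Pie-chart glyph visualization of single-cell embeddings.

## The problem

The standard way to show marker-gene expression on a UMAP or t-SNE plot is
one single-colored panel per gene. That works for one or two markers and
collapses for a 12-gene biomarker panel or a 145-gene differentiation
program: the figure becomes a wall of near-identical scatter plots that the
reader has to integrate mentally. scPies draws the whole panel in **one**
plot by replacing each cell's dot with a small pie chart at the cell's
embedding coordinates:

- each **slice** is one gene from one or more user-provided marker lists,
  and its angle is the gene's share of the cell's normalized expression;
- slice **color intensity** and glyph **size** encode expression magnitude;
- colors are assigned automatically (one per gene from a colormap, or one
  per list), with an auto-generated legend;
- a **cluster mode** ("big pies") aggregates to one pie per cell cluster —
  the composition of the cluster's mean expression, sized by cell count.

It is aimed at anyone with an exported count matrix and 2-D coordinates
(from Seurat, Scanpy, or any other toolchain); scPies deliberately does no
preprocessing, clustering or dimensionality reduction of its own.

## The normalization at the core

Plotting two gene lists of unequal length (say 8 class 1 vs 4 class 2
biomarkers) is biased: at equal per-gene expression the longer list paints
twice the pie. scPies corrects this by rescaling every expression value *X*
of a gene in a list of *N*<sub>list</sub> genes (out of *N*<sub>total</sub>
genes across all lists) to

> *X*<sub>norm</sub> = *X* · *N*<sub>total</sub> / *N*<sub>list</sub>

and defines slice fractions as
*X*<sub>norm,i</sub> / Σ<sub>j</sub> *X*<sub>norm,j</sub>. Under this
weighting, *g* lists whose genes are all expressed at a common value get
exactly 1/*g* of the pie each, regardless of list sizes.

## Worked example

The package ships the two uveal-melanoma biomarker lists as example data and
a synthetic-data generator (Gaussian blobs with negative-binomial gene
programs), so everything below runs offline.

```r
library(scPies)

spec <- readGeneLists(
  c(system.file("extdata", "uveal_melanoma_class1.txt", package = "scPies"),
    system.file("extdata", "uveal_melanoma_class2.txt", package = "scPies")),
  colorRules = c("winter", "autumn"),
  groupNames = c("class1", "class2"))
spec
#> GeneListSpec with 2 group(s), 12 gene(s) total
#>   class1 [winter]: EIF1B, FXR1, ID2, LMCD1, LTA4H, MTUS1, ... (8 genes)
#>   class2 [autumn]: CDH1, ECM1, HTR2B, RRAB31
```

With every one of the 12 genes at the same value, each class 1 gene gets
1/16 of the pie and each class 2 gene 1/8 — the two lists weigh 0.5 each:

```r
computeFractions(setNames(rep(2, 12), unlist(groupGenes(spec))), spec)[1:4]
#>  EIF1B   FXR1    ID2  LMCD1
#> 0.0625 0.0625 0.0625 0.0625
```

A full cell-mode plot on simulated data (3 clusters × 100 cells, one
program gene per cluster):

```r
fix <- simulateCells(seed = 1)
comp <- buildCellCompositions(fix$sce, fix$spec)
comp
#> CellCompositionSet: 300 cell(s) x 3 gene(s), 7 empty cell(s)
#>   genes: PRG1.1, PRG2.1, PRG3.1

round(fractions(comp)[1:3, ], 4)
#>      [,1] [,2] [,3]
#> [1,]  1.0  0.0    0
#> [2,]  1.0  0.0    0
#> [3,]  0.8  0.2    0

asg    <- assignColors(fix$spec)
glyphs <- layoutGlyphs(comp, asg)
wedges(glyphs[[1]])   # cell 1 expresses only its home program gene
#>          gene start end    fill
#> PRG1.1 PRG1.1     0 360 #CCCCFF

renderFigure(glyphs, buildLegendEntries(asg, fix$spec),
             renderConfig(), "cells.svg")
writeCompositionTable(comp, "composition.csv")
```

The first three cells put 100%, 100% and 80% of their pie on `PRG1.1`, the
program gene of their home cluster; the single full-circle wedge of cell 1
is lightened from the map color toward white (`#CCCCFF`) because that cell's
expression sits low on the gene's intensity scale. Cluster mode:

```r
summarizeClusters(fix$sce, fix$spec)
#> ClusterSummarySet with 3 cluster(s)
#>   C1: 100 cells, centroid (5.05, 0.0258)
#>   C2: 100 cells, centroid (-2.52, 4.31)
#>   C3: 100 cells, centroid (-2.49, -4.35)
```

The same pipeline is scriptable from a shell via
`inst/scripts/scpies` (`plot-cells`, `plot-clusters`, `make-fixture`), e.g.

```sh
Rscript inst/scripts/scpies plot-cells \
  --expression expr.csv --coords umap.csv \
  --gene-list class1.txt --color winter \
  --gene-list class2.txt --color autumn \
  --out figure.svg --composition-out composition.csv
```

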