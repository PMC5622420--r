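# phylomap

Reference phylogenies have outgrown tree viewers. An rRNA guide tree of the
kind distributed by large ribosomal-database projects holds 10^5–10^6
sequences plus tens of thousands of named clades, and biologists need to
*browse* it — pan, zoom, identify the taxon under the cursor, search by
accession or name — rather than render it once. `phylomap` implements the
backend of such a browser as an ordinary R package: it turns an annotated
Newick tree into a zoomable map (in the web-mapping sense) and answers every
navigation, context, and search query a front-end would issue, with no server
and no external data.

It is aimed at people who maintain or study large taxonomically annotated
trees: database curators preparing a tree for interactive display, and
developers who need exact, testable semantics for tree-map queries.

## The model

The tree is drawn as a rectangular phylogram in a fixed **world coordinate
system**:

* `x(v) = Σ branch lengths from the root to v` (branch-length units; root at
  x = 0) — so a horizontal scale bar is meaningful at any zoom;
* `y(leaf k) = k` in file order (leaf-index units, pitch 1.0);
  `y(internal) = (y(first child) + y(last child)) / 2` — vertical geometry is
  independent of branch lengths.

Every non-root node owns a horizontal edge segment, every internal node a
vertical connector, and every annotated taxon an axis-aligned **taxon
rectangle**: y spanning its clade's first-to-last leaf index, x the tight
range over the clade's nodes and edges (incoming edge included),
colour-coded by rank. The extent is padded (never stretched) to a square
world, which maps at zoom *z* onto a 2^z × 2^z grid of 256-px tiles with one
scale for both axes; features are indexed for exact window queries, rendered
into a deterministic PNG tile pyramid under level-of-detail rules, and
queried per viewport: taxon bar (full path plus sequence counts under a
point), taxonomy brackets (rank-ordered, domain rightmost), minimap
rectangle, scale bar (largest {1,2,5}·10^k value spanning 50–150 px).

Search follows the conventions of sequence databases: accession **prefix**
search understanding `<accession>.<start>.<stop>` addresses, species-name
and taxon-name **substring** search, and taxonomic-path search that returns
only the highest-rank (ancestor-suppressed) matches — all case-insensitive,
all results ordered by vertical position and driven through a cyclic
next/previous results navigator. A fixture generator produces realistic
annotated trees at any size, so everything here runs from a seed.

## Worked example

```r
library(phylomap)

tree <- generate_fixture(500, seed = 42)   # or read_tree_map("tree.nwk", "meta.tsv")
tree
#> <phylomap_tree> 500 leaves, 499 internal nodes, 32 annotated taxa
#> ranks: domain > phylum > class > order > family > genus
#> taxa per rank: domain=2, phylum=3, class=5, order=8, family=9, genus=5

lay   <- compute_layout(tree)
rects <- compute_taxon_rects(tree, lay)
rects[1:2, c("taxon_name", "rank", "y_lo", "y_hi", "sequence_count", "color")]
#>   taxon_name rank    y_lo  y_hi sequence_count color
#> 1 Domain001  domain     0    16             17 #4D4D4D
#> 2 Domain002  domain    17   499            483 #4D4D4D

idx <- build_index(lay, rects)
build_pyramid(idx, z_max = 3, out_dir = "tiles")
#> <phylomap_pyramid> 15/15 tiles written, zoom 0..3, at tiles
```

The two domain rectangles partition the 500 leaves (17 + 483); the pyramid
wrote all 15 candidate tiles (the tree occupies a thin column of the square
world, so only one tile column per zoom intersects it). Queries against the
built map:

```r
taxon_at_point(rects, 0.02, 100)          # taxon bar under the cursor
#>   taxon_id taxon_name rank   sequence_count
#> 1      518 Domain002  domain            483
#> 2      519 Phylum003  phylum            482
#> 3      520 Class004   class             405
#> ...                                      (full path, domain first)

scale_bar(world_transform(lay$extent, zoom = 6))
#> $length 2     $width_px 64    # 2 branch-length units span 64 px at z6

res <- search_sequences_by_accession(tree, lay, "QK4")
res
#> <phylomap_result> sequence search, 1 hit(s), cursor at 1
#>   id      name                 accession start stop     x     y
#> 1 L000100 Genus005 species0100 QK414573      1  947 0.138    99

navigate(res, "next", lay$extent)$viewport
#> window x [0, 23.86], y [87.07, 110.93], zoom 6   (hit centred on screen)
```

`tidy()`/`glance()` give tabular views of every object
(`glance(lay)` → 500 leaves, 999 nodes, 1497 edge segments, x_max 0.497),
and `autoplot(lay, rects = rects, hits = res)` draws the phylogram with
rank-coloured rectangles and hit markers. The same operations are scriptable
from a shell via `inst/exec/phylomap`
(`fixture`, `build`, `tiles`, `search`, `query`, `browse-phyla`, `navigate`,
`report`), with JSON on stdout and exit codes 0/2/3/4/5 for
ok/usage/parse/consistency/I-O.

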