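---
title: "phylomap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylomap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomap)
```

## What the package computes

`phylomap` treats a large annotated phylogeny the way a web map treats the
Earth: geometry is laid out once in a fixed world coordinate system, then
served through resolution-dependent views. The pipeline has four stages —
layout, taxon rectangles, spatial index, tile pyramid — and two query
families on top (viewport context and search). This vignette records the
model, its assumptions, the tunable parameters, and the design decisions
that were genuinely open, so that a maintainer can see *why* the code is
shaped as it is.

## The world coordinate system

A rectangular phylogram assigns:

* **x**, in branch-length units: `x(root) = 0`,
  `x(v) = x(parent(v)) + branch_length(v)`. This is the only axis on which
  distances are biologically meaningful, which is why the on-screen scale
  bar refers to horizontal extents only.
* **y**, in leaf-index units: leaf *k* (0-based, in the order leaves appear
  in the Newick file) sits at `y = k`; an internal node sits at the midpoint
  of its *first and last* child's y.

Assumptions: a single root; non-negative branch lengths (missing lengths
are zero-filled with a warning, because every node needs an x coordinate);
leaf order is meaningful and preserved — the package never ladderizes or
reorders, so the same input always produces the same picture.

Midpoint-of-extremes (rather than mean-of-children) for internal y is the
standard square-edge phylogram convention: it guarantees the vertical
connector of a node spans exactly its children's range, so edges never
cross. With this choice the whole layout is computed in one post-order pass
(child y before parent y) plus one pre-order pass (parent x before child
x), and is deterministic.

**Taxon rectangles.** Each annotated clade gets the axis-aligned box
`[x_lo, x_hi] × [y_lo, y_hi]` with y spanning the clade's first-to-last
leaf index and x the *tight* range over all of the clade's nodes and edge
segments. The clade root's incoming horizontal edge is included in x_lo —
otherwise the rectangle would clip the very edge that attaches the clade to
the rest of the tree. Rectangles therefore nest in y along the annotation
hierarchy, and `sequence_count` is exactly the number of leaves enclosed.
Zero-length branches are legal; they produce coincident x coordinates and,
possibly, sibling rectangles that touch. Containment tests are *closed*
(boundaries count) so hit-testing is deterministic; where overlapping
rectangles both contain a probe point, the most specific (lowest-rank) one
wins, with ties broken toward the smaller y — the alternative (top-most
wins) is equally defensible but less informative for a taxon bar.

## The square world and the tile pyramid

Guide-tree layouts are extremely tall and thin: x spans a few branch-length
units while y spans one unit per sequence. Two options exist for mapping
this onto square tiles: stretch each axis independently, or keep one scale
and pad. `phylomap` pads: the occupied extent is embedded in a square of
side `max(x_extent, y_extent) * (1 + pad_frac)` and a single scale factor
serves both axes, so a horizontal branch length means the same number of
pixels anywhere and at any aspect. The cost is that the tree occupies a
narrow column of the world and most tiles at any zoom are empty; the
pyramid builder handles this by enumerating only tiles whose window
intersects the occupied extent and recording skipped (fully transparent)
tiles in the manifest. Padding is applied to the right and bottom only, so
the world origin (0, 0) is a fixed point of every zoom's pixel transform —
an invariant worth more than visual centring, which a front-end can apply
itself by offsetting its initial viewport.

At zoom *z* the square maps onto a `2^z × 2^z` grid of `tile_size`-pixel
tiles (`tile_size` defaults to 256, the web-map dialect), giving
`scale = 2^z · tile_size / padded_side` pixels per world unit. Tile edges
are computed as `t · padded_side / 2^z`, so adjacent windows share bit-equal
boundaries and the grid partitions the world exactly.

**Rendering.** Tiles are RGBA rasters drawn bottom-up: taxon rectangles
(rank colour at 25% opacity, so nested ranks remain distinguishable),
then edges as opaque 1-px lines without anti-aliasing, then sequence
labels in an embedded 5×7 bitmap font. All drawing happens in *global*
pixel coordinates (`floor(world · scale)`) and is then offset into the
tile, which makes clipping on both sides of a tile border consistent —
this is what the stitch test relies on: assembling the 4×4 zoom-2 tiles
and box-downsampling reproduces the zoom-0 thumbnail up to the residue of
1-px lines. Anti-aliasing is deliberately off and text is deliberately a
bitmap font rendered by the package itself: both choices make tile bytes a
pure function of the inputs, so two builds can be compared byte for byte.

**Level of detail** (`lod_policy()`):

| parameter | unit | default | role |
|---|---|---|---|
| `min_leaf_pitch_px` | px | 8 | sequence labels appear once adjacent leaves are ≥ this far apart |
| `min_rect_height_px` | px | 2 | taxon rectangles shorter than this are not drawn |
| `min_bracket_height_px` | px | 12 | brackets shorter than this lose their text label (the taxon is still reported, for tooltips) |
| `label_font_px` | px | 10 | nominal label height; the 5×7 font is integer-scaled to approximate it |

All thresholds compare a world size multiplied by the zoom's scale, so
every visibility decision is monotone in zoom: nothing ever disappears as
the user zooms in.

## Viewport queries

* **Taxon bar** (`taxon_at_point`): all rectangles containing the point,
  reduced to the most specific, then expanded to its ancestor chain via the
  annotation hierarchy (not via containment, which overlapping siblings
  would confuse), reported domain-first with sequence counts.
* **Brackets** (`brackets_for_viewport`): a taxon "crosses" the view iff
  its y-interval intersects the viewport's y-range — x is ignored, because
  brackets live in a fixed right-hand gutter. Columns are assigned per rank
  *present in the result*, compacted, domain in column 0 (rightmost):
  compaction keeps the gutter narrow when intermediate ranks are absent,
  and the column order is still a strict embedding of the rank order.
* **Minimap** (`minimap_rect`): the viewport as fractions of the occupied
  extent; affine and invertible, so the front-end can drag the minimap
  rectangle and invert the map.
* **Scale bar** (`scale_bar`): the largest value `{1, 2, 5} · 10^k` whose
  pixel width falls in [50, 150] px — the standard cartographic nice-number
  convention; when no candidate fits the band (extreme zooms), the largest
  value not exceeding the upper bound is used so the bar never overflows.

## Search semantics

Accessions are addressed as `<accession>.<start>.<stop>`. The parser takes
the *rightmost two all-digit dot-fields* as positions and everything before
them (dots preserved) as the prefix; a single trailing numeric field is
treated as part of the accession (versioned accessions like `NR_074334.12`
would otherwise be torn apart). Prefix matching is case-insensitive, and
the empty prefix is universal. Substring searches (species name, taxon
name, path) are case-insensitive too, but the empty query is *rejected*
for them: an empty substring matches everything, and a whole-tree result
set is never what a user meant — this asymmetry with the accession search
is deliberate and documented here.

Path search implements ancestor suppression: every taxon nested inside a
matching group also matches textually, so a candidate is returned only if
no proper ancestor is itself a candidate. Two properties pin this down:
(a) no returned taxon has a candidate proper ancestor, and (b) every
candidate is a descendant-or-self of some returned taxon; both are checked
against brute-force scans in the tests.

The results navigator keeps hits sorted by y (ties by ID, so the order is
total and stable) with a cursor; `next`/`previous` wrap cyclically — end
behaviour had to be chosen, and wrapping avoids a dead end at the last hit.
Target viewports centre the current hit at the smallest zoom giving it a
comfortable on-screen size (32 px by default), clamped by shifting (never
shrinking) into the world square.

## The fixture generator

`generate_fixture()` emulates the statistical shape of an rRNA guide tree
so the pipeline can be exercised at any size without external data:

* topology by random sequential attachment — each new leaf splits a
  uniformly chosen branch (split point uniform, pendant length fresh), the
  classic null model for unstructured tree growth;
* branch lengths exponential with mean 0.05 substitutions/site, keeping
  root-to-leaf depths of large trees in the 0.5–2 range typical of rRNA
  phylogenies;
* annotations assigned top-down: the root's children become domains (or the
  root itself, when a leaf hangs directly off it, so every path still
  starts at a domain); below that, each internal child of an annotated node
  is annotated at the next rank with probability 0.9 and passed through
  otherwise, producing taxonomic paths of varying depth;
* per-leaf records: unique accessions (2 letters + 6 digits), `start = 1`,
  `stop` uniform in [900, 1600] (full-length SSU-scale coordinates), and a
  binomial-style name derived from the most specific annotation above the
  leaf. The single-leaf tree is special-cased as a chain of one node per
  rank so even the degenerate case carries a full-depth path.

Everything is a deterministic function of the seed, and the caller's RNG
state is left untouched.

What the generator does **not** emulate: multifurcating named groups with
hundreds of sibling taxa (the grown topology is binary, so a six-rank
hierarchy yields tens of taxa, not the tens of thousands a curated taxonomy
attaches to a million-sequence tree); rate heterogeneity across clades;
non-unique or structured accession prefixes; and any sequence content.
Passing tests therefore demonstrate correctness of geometry and query
semantics at realistic *scale*, not fidelity to any particular database's
taxonomy.

## Numerical choices and degenerate inputs

* Branch lengths round-trip through Newick at 12 significant digits; the
  tests require agreement to 1e-9 absolute, and geometry oracles are
  checked at 1e-9 (sums of doubles along root paths are exact to ~1e-15 at
  these depths).
* A single-leaf layout has zero y-extent; transforms guard the degenerate
  square (`side = max(extent, …)` with a floor) so zoom math never divides
  by zero.
* Window queries use closed intervals everywhere, matching the closed
  rectangles of hit-testing.
* The y-bucket index (256 buckets, features spanning more than 8 buckets
  kept in an always-checked side list) is an accelerator only; its contract
  is extensional equality with a linear scan, which the tests enforce on
  random windows.
* Newick parsing is delegated to `ape`, with two repairs applied on top:
  a pre-scan reports unbalanced parentheses with a character offset, and —
  because `ape::read.tree` mis-orders internal labels and branch lengths
  along unary (singleton) chains — labels are always, and lengths are
  (when singletons are present) re-derived from the text, using the fact
  that the *i*-th `(` opens exactly the *i*-th internal node in preorder.

## Problem sizes used by the tests

The suite checks the geometry oracles on 50 random fixtures of 10–1,000
leaves, the spatial index on 100 random windows per fixture, search on
10,000-leaf fixtures with 50 random queries per mode, brackets on 200
random viewports, and runs one full build of a 100,000-leaf fixture tiled
to zoom 6 with queries against it — sizes chosen so the whole suite
completes in a few minutes on a single core while still exercising the
index and renderer well beyond the regime where naive implementations
break down.

## Known limitations

* Group folding/collapsing is out of scope: the tree is always fully
  expanded (the fixed leaf-index y-axis is what makes tiles cacheable).
* Tiles are raster-only; there is no vector-tile or on-demand-server mode,
  though `render_tile()` is a pure function an HTTP wrapper could call.
* The feedback store is a local JSON-lines append log — a data contract,
  not a ticketing system.
* Taxon rectangles of sibling clades can overlap in x when branch lengths
  are zero; the taxon bar resolves this most-specific-first, but a
  front-end drawing translucent rectangles will simply show the overlap.
* The bitmap font covers A–Z, digits and basic punctuation; other
  characters render as filled boxes rather than glyphs.
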