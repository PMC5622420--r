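#' Construct a viewport
#'
#' A viewport is the argument of all context queries: a world-coordinate
#' window plus the zoom level at which it is displayed. The window must
#' be non-degenerate and lie within the padded world square.
#'
#' @param x_lo,x_hi,y_lo,y_hi World coordinates of the window edges
#'   (x in branch-length units, y in leaf-index units).
#' @param zoom Non-negative integer zoom level.
#' @return A `phylomap_viewport` list with `window` (named numeric) and
#'   `zoom`.
#' @export
viewport <- function(x_lo, x_hi, y_lo, y_hi, zoom) {
  if (!is_count_(zoom) || zoom < 0) abort_query("zoom must be a non-negative integer")
  if (!(x_lo < x_hi) || !(y_lo < y_hi)) {
    abort_query("viewport window must satisfy x_lo < x_hi and y_lo < y_hi")
  }
  structure(list(
    window = c(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
    zoom = as.integer(zoom)
  ), class = "phylomap_viewport")
}

#' Taxon bar: the full taxonomic path under a point
#'
#' Finds every annotated taxon whose rectangle contains the world point
#' (rectangles are closed, so boundary points count), takes the most
#' specific of them, and returns its full ancestor chain domain-first,
#' with per-taxon sequence counts -- the content of the viewer's taxon
#' bar. Returns a zero-row tibble when no rectangle contains the point.
#' Where sibling rectangles overlap (possible with zero-length branches)
#' the most specific containing taxon wins; ties break to the smallest
#' `y_lo`.
#'
#' @param rects Taxon rectangles from [compute_taxon_rects()].
#' @param x,y The query point in world coordinates.
#' @return A tibble, one row per path element, domain first: `taxon_id`,
#'   `taxon_name`, `rank`, `sequence_count`.
#' @export
taxon_at_point <- function(rects, x, y) {
  inside <- rects$x_lo <= x & x <= rects$x_hi &
    rects$y_lo <= y & y <= rects$y_hi
  hit <- rects[inside, ]
  if (nrow(hit) == 0L) {
    return(tibble(taxon_id = integer(), taxon_name = character(),
                  rank = character(), sequence_count = integer()))
  }
  hit <- arrange(hit, desc(.data$rank_index), .data$y_lo)
  tip <- hit[1, ]
  # ancestor chain via parent_taxon links (not containment), domain-first
  chain <- integer(0)
  cur <- tip$taxon_id
  repeat {
    chain <- c(cur, chain)
    row <- rects[match(cur, rects$taxon_id), ]
    if (is.na(row$parent_taxon)) break
    cur <- row$parent_taxon
  }
  out <- rects[match(chain, rects$taxon_id), ]
  select(out, "taxon_id", "taxon_name", "rank", "sequence_count")
}

#' Taxonomy brackets for the current viewport
#'
#' One bracket per taxon whose y-interval intersects the viewport's
#' y-range (x plays no role: brackets live in a fixed right-hand gutter).
#' `y_span_visible` is the intersection, clipped to the viewport;
#' `clipped_top`/`clipped_bottom` flag truncation at the viewport edges.
#' Brackets are stacked right-to-left by rank: column 0 (rightmost) is
#' the most generic rank present in the result, and each successively
#' lower rank present gets the next column (compacted, so absent ranks
#' consume no gutter width). `label_shown` is FALSE when the visible
#' pixel height at the viewport zoom is below `min_bracket_height_px`;
#' the bracket row is still returned so the name stays available for a
#' tooltip.
#'
#' @inheritParams taxon_at_point
#' @param viewport A [viewport()].
#' @param lod A [lod_policy()].
#' @param transform A `phylomap_transform` at the viewport's zoom, used
#'   to convert world height to pixels.
#' @return A tibble sorted by `column` then `y_lo`: `taxon_id`,
#'   `taxon_name`, `rank`, `column`, `y_lo`, `y_hi` (the visible span),
#'   `label_shown`, `clipped_top`, `clipped_bottom`, `sequence_count`.
#' @export
brackets_for_viewport <- function(rects, viewport, transform,
                                  lod = lod_policy()) {
  stopifnot(inherits(viewport, "phylomap_viewport"),
            inherits(transform, "phylomap_transform"))
  w <- viewport$window
  hit <- rects[intervals_overlap_(rects$y_lo, rects$y_hi, w[["y_lo"]], w[["y_hi"]]), ]
  if (nrow(hit) == 0L) {
    return(tibble(taxon_id = integer(), taxon_name = character(),
                  rank = character(), column = integer(), y_lo = numeric(),
                  y_hi = numeric(), label_shown = logical(),
                  clipped_top = logical(), clipped_bottom = logical(),
                  sequence_count = integer()))
  }
  ranks_present <- sort(unique(hit$rank_index))
  column <- match(hit$rank_index, ranks_present) - 1L
  y_lo_vis <- pmax(hit$y_lo, w[["y_lo"]])
  y_hi_vis <- pmin(hit$y_hi, w[["y_hi"]])
  scale_y <- transform$scale_y
  out <- tibble(
    taxon_id = hit$taxon_id,
    taxon_name = hit$taxon_name,
    rank = hit$rank,
    column = column,
    y_lo = y_lo_vis,
    y_hi = y_hi_vis,
    label_shown = (y_hi_vis - y_lo_vis) * scale_y >= lod$min_bracket_height_px,
    clipped_top = hit$y_lo < w[["y_lo"]],
    clipped_bottom = hit$y_hi > w[["y_hi"]],
    sequence_count = hit$sequence_count
  )
  arrange(out, .data$column, .data$y_lo)
}

#' Minimap rectangle: the viewport as fractions of the whole tree
#'
#' Maps the viewport window onto the unit square spanned by the occupied
#' extent, for drawing the navigation bar's "you are here" rectangle.
#' The mapping is affine and invertible.
#'
#' @inheritParams brackets_for_viewport
#' @param extent The occupied extent (from [compute_layout()]).
#' @return Named numeric `x_lo`, `x_hi`, `y_lo`, `y_hi`, each in [0, 1]
#'   when the viewport lies within the extent.
#' @export
minimap_rect <- function(viewport, extent) {
  stopifnot(inherits(viewport, "phylomap_viewport"))
  w <- viewport$window
  dx <- extent[["x_max"]] - extent[["x_min"]]
  dy <- extent[["y_max"]] - extent[["y_min"]]
  if (dx <= 0) dx <- 1
  if (dy <= 0) dy <- 1
  c(
    x_lo = (w[["x_lo"]] - extent[["x_min"]]) / dx,
    x_hi = (w[["x_hi"]] - extent[["x_min"]]) / dx,
    y_lo = (w[["y_lo"]] - extent[["y_min"]]) / dy,
    y_hi = (w[["y_hi"]] - extent[["y_min"]]) / dy
  )
}

#' Scale bar for the current zoom
#'
#' Picks the "nice" branch-length value -- of the form 1, 2 or 5 times a
#' power of ten -- whose pixel width at the given transform falls within
#' `[min_px, max_px]`, preferring the largest such value; if none fits
#' the band, the largest value not exceeding `max_px` is returned. This
#' gives the on-screen reference for interpreting horizontal branch
#' lengths at the current zoom.
#'
#' @param transform A `phylomap_transform`.
#' @param min_px,max_px Pixel band for the bar width.
#' @return A list with `length` (branch-length units) and `width_px`
#'   (integer pixels).
#' @export
scale_bar <- function(transform, min_px = 50, max_px = 150) {
  sx <- transform$scale_x
  if (!is.finite(sx) || sx <= 0) abort_query("transform has non-positive scale_x")
  ks <- seq(floor(log10(1 / sx)) - 2, ceiling(log10(max_px / sx)) + 2)
  cand <- sort(as.vector(outer(c(1, 2, 5), 10^ks)))
  width <- cand * sx
  in_band <- width >= min_px & width <= max_px
  len <- if (any(in_band)) max(cand[in_band]) else {
    fits <- width <= max_px
    if (!any(fits)) cand[1] else max(cand[fits])
  }
  list(length = len, width_px = as.integer(round(len * sx)))
}
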