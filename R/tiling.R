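#' World-to-pixel transform for the tile pyramid
#'
#' The occupied extent (x in branch-length units, y in leaf-index units)
#' is padded, not stretched, to a square "world" so that one scale factor
#' serves both axes and branch lengths remain comparable anywhere in the
#' view. Padding is added to the right and bottom only, so the world
#' origin (0, 0) maps to pixel (0, 0) at every zoom. At zoom z the padded
#' square maps exactly onto a 2^z x 2^z grid of `tile_size`-pixel tiles:
#' `scale = 2^z * tile_size / padded_side` pixels per world unit, for
#' both axes. Pixel x grows rightward, pixel y downward.
#'
#' @param extent Named numeric with `x_min`, `x_max`, `y_min`, `y_max`
#'   (as produced by [compute_layout()]).
#' @param zoom Non-negative integer zoom level.
#' @param tile_size Tile edge in pixels (default 256).
#' @param pad_frac Fractional margin added beyond the larger extent side
#'   (default 0.02) so boundary features never fall on the world edge.
#' @return A `phylomap_transform` list: `zoom`, `tile_size`, `scale_x`,
#'   `scale_y` (equal, pixels per world unit), `padded_side`,
#'   `padded_extent` (the square window), and the original `extent`.
#' @examples
#' tr <- generate_fixture(20, seed = 1)
#' world_transform(compute_layout(tr)$extent, zoom = 2)
#' @export
world_transform <- function(extent, zoom, tile_size = 256L, pad_frac = 0.02) {
  if (!is_count_(zoom) || zoom < 0) abort_config("zoom must be a non-negative integer")
  side_occ <- max(extent[["x_max"]] - extent[["x_min"]],
                  extent[["y_max"]] - extent[["y_min"]])
  if (side_occ <= 0) side_occ <- 1   # degenerate single-point layouts
  padded <- side_occ * (1 + pad_frac)
  scale <- (2^zoom * tile_size) / padded
  structure(list(
    zoom = as.integer(zoom),
    tile_size = as.integer(tile_size),
    scale_x = scale,
    scale_y = scale,
    padded_side = padded,
    padded_extent = c(x_min = 0, x_max = padded, y_min = 0, y_max = padded),
    extent = extent
  ), class = "phylomap_transform")
}

#' Tile addressing over the padded world
#'
#' `tile_window()` returns the world-coordinate window of tile
#' `(z, tx, ty)`; tiles at one zoom partition the padded square exactly
#' (shared edges, no gaps). `tile_address()` validates an address.
#'
#' @param transform A `phylomap_transform` (its `zoom` is ignored here;
#'   the window depends only on `padded_side`).
#' @param z,tx,ty Zoom and tile column/row, `tx`, `ty` in `[0, 2^z)`.
#' @return `tile_window()`: named numeric `x_lo`, `x_hi`, `y_lo`, `y_hi`.
#' @export
tile_window <- function(transform, z, tx, ty) {
  tile_address(z, tx, ty)
  side <- transform$padded_side / 2^z
  c(x_lo = tx * side, x_hi = (tx + 1) * side,
    y_lo = ty * side, y_hi = (ty + 1) * side)
}

#' @rdname tile_window
#' @export
tile_address <- function(z, tx, ty) {
  if (!is_count_(z) || z < 0) abort_address("zoom must be a non-negative integer")
  if (!is_count_(tx) || !is_count_(ty) || tx < 0 || ty < 0 ||
      tx >= 2^z || ty >= 2^z) {
    abort_address(sprintf("tile (%s, %s) out of range for zoom %s", tx, ty, z))
  }
  invisible(list(z = as.integer(z), tx = as.integer(tx), ty = as.integer(ty)))
}

#' Level-of-detail policy
#'
#' Zoom-dependent drawing rules: a sequence (leaf) label is shown only
#' when the leaf pitch (pixels between adjacent leaves) reaches
#' `min_leaf_pitch_px`; a taxon rectangle is drawn only when its pixel
#' height reaches `min_rect_height_px`; a taxonomy bracket gets its text
#' label only when its visible pixel height reaches
#' `min_bracket_height_px` (the bracket itself, and the taxon behind it,
#' are still reported so a tooltip can show the name). `label_font_px`
#' is the nominal label height used by the tile renderer.
#'
#' @param min_leaf_pitch_px,min_rect_height_px,min_bracket_height_px,label_font_px
#'   Positive pixel thresholds.
#' @return A `phylomap_lod` list.
#' @export
lod_policy <- function(min_leaf_pitch_px = 8, min_rect_height_px = 2,
                       min_bracket_height_px = 12, label_font_px = 10) {
  vals <- c(min_leaf_pitch_px, min_rect_height_px, min_bracket_height_px,
            label_font_px)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_config("all LOD thresholds must be positive")
  }
  structure(list(
    min_leaf_pitch_px = min_leaf_pitch_px,
    min_rect_height_px = min_rect_height_px,
    min_bracket_height_px = min_bracket_height_px,
    label_font_px = label_font_px
  ), class = "phylomap_lod")
}

#' Build the spatial feature index
#'
#' Collects every drawable feature -- horizontal and vertical edge
#' segments, leaf label anchors, and taxon rectangles -- into one table
#' with a world-coordinate bounding box per feature, bucketed on y for
#' fast window queries (features spanning many buckets are kept in a
#' small always-checked set). Window queries return exactly the features
#' whose (closed) bounding box intersects the window.
#'
#' @inheritParams compute_layout
#' @param layout A `phylomap_layout`.
#' @param rects Taxon rectangles from [compute_taxon_rects()]; pass
#'   `NULL` to index geometry only.
#' @param tile_size,pad_frac Passed to [world_transform()] when the index
#'   is used for rendering or LOD decisions.
#' @return A `phylomap_index` list: `features` (tibble: `feature_id`,
#'   `kind` in `edge_h`/`edge_v`/`leaf_label`/`taxon_rect`, `ref`,
#'   `name`, `rank`, `color`, `x_lo`, `x_hi`, `y_lo`, `y_hi`), `extent`,
#'   `n_leaves`, `tile_size`, `pad_frac`.
#' @examples
#' tr <- generate_fixture(20, seed = 1)
#' lay <- compute_layout(tr)
#' idx <- build_index(lay, compute_taxon_rects(tr, lay))
#' nrow(idx$features)
#' @export
build_index <- function(layout, rects = NULL, tile_size = 256L, pad_frac = 0.02) {
  stopifnot(inherits(layout, "phylomap_layout"))
  ed <- layout$edges
  feats_edges <- tibble(
    kind = ifelse(ed$kind == "h", "edge_h", "edge_v"),
    ref = as.character(ed$node),
    name = NA_character_,
    rank = NA_character_,
    color = NA_character_,
    x_lo = pmin(ed$x0, ed$x1), x_hi = pmax(ed$x0, ed$x1),
    y_lo = pmin(ed$y0, ed$y1), y_hi = pmax(ed$y0, ed$y1)
  )
  leaves <- layout$nodes[layout$nodes$is_leaf, ]
  feats_leaves <- tibble(
    kind = "leaf_label",
    ref = leaves$label,
    name = paste(leaves$accession, leaves$full_name),
    rank = NA_character_,
    color = NA_character_,
    x_lo = leaves$x, x_hi = leaves$x,
    y_lo = leaves$y, y_hi = leaves$y
  )
  feats <- bind_rows(feats_edges, feats_leaves)
  if (!is.null(rects) && nrow(rects)) {
    feats <- bind_rows(feats, tibble(
      kind = "taxon_rect",
      ref = as.character(rects$taxon_id),
      name = rects$taxon_name,
      rank = rects$rank,
      color = rects$color,
      x_lo = rects$x_lo, x_hi = rects$x_hi,
      y_lo = rects$y_lo, y_hi = rects$y_hi
    ))
  }
  feats$feature_id <- seq_len(nrow(feats))
  feats <- feats[, c("feature_id", "kind", "ref", "name", "rank", "color",
                     "x_lo", "x_hi", "y_lo", "y_hi")]

  max_lab <- if (nrow(feats_leaves)) max(nchar(feats_leaves$name), 0L) else 0L
  idx <- structure(list(
    features = feats,
    extent = layout$extent,
    n_leaves = layout$n_leaves,
    tile_size = as.integer(tile_size),
    pad_frac = pad_frac,
    max_label_px = max_lab * 6L + 8L   # widest label at font scale 1
  ), class = "phylomap_index")
  idx$buckets <- index_buckets_(idx)
  idx
}

# y-bucket acceleration structure: small features binned by y interval,
# features spanning > span_cap buckets always checked.
index_buckets_ <- function(idx, n_buckets = 256L, span_cap = 8L) {
  side <- max(idx$extent[["x_max"]], idx$extent[["y_max"]], 1e-12)
  h <- side / n_buckets
  f <- idx$features
  b_lo <- pmin(pmax(floor(f$y_lo / h), 0), n_buckets - 1L)
  b_hi <- pmin(pmax(floor(f$y_hi / h), 0), n_buckets - 1L)
  span <- b_hi - b_lo + 1L
  large <- which(span > span_cap)
  small <- which(span <= span_cap)
  reps <- span[small]
  member_bucket <- unlist(mapply(seq.int, b_lo[small], b_hi[small],
                                 SIMPLIFY = FALSE), use.names = FALSE)
  member_feat <- rep.int(f$feature_id[small], reps)
  ord <- order(member_bucket)
  member_bucket <- member_bucket[ord]
  member_feat <- member_feat[ord]
  starts <- findInterval(seq_len(n_buckets) - 1L - 0.5, member_bucket) + 1L
  ends <- findInterval(seq_len(n_buckets) - 0.5, member_bucket)
  list(n_buckets = n_buckets, h = h, large = large,
       member_feat = member_feat, starts = starts, ends = ends)
}

#' Query the index with a world-coordinate window
#'
#' Returns exactly the features whose closed bounding box intersects the
#' closed window, equivalent to a linear scan over all features.
#'
#' @param index A `phylomap_index`.
#' @param window Named numeric `x_lo`, `x_hi`, `y_lo`, `y_hi`.
#' @return The matching rows of `index$features`, in `feature_id` order.
#' @export
window_query <- function(index, window) {
  stopifnot(inherits(index, "phylomap_index"))
  f <- index$features
  b <- index$buckets
  b_lo <- max(min(floor(window[["y_lo"]] / b$h), b$n_buckets - 1L), 0L)
  b_hi <- max(min(floor(window[["y_hi"]] / b$h), b$n_buckets - 1L), 0L)
  if (window[["y_hi"]] < 0 || window[["y_lo"]] > b$n_buckets * b$h) {
    cand <- b$large
  } else {
    s <- b$starts[b_lo + 1L]
    e <- b$ends[b_hi + 1L]
    cand <- c(if (s <= e) unique(b$member_feat[s:e]) else integer(0), b$large)
  }
  cand <- sort(cand)
  fc <- f[cand, ]
  hit <- intervals_overlap_(fc$x_lo, fc$x_hi, window[["x_lo"]], window[["x_hi"]]) &
    intervals_overlap_(fc$y_lo, fc$y_hi, window[["y_lo"]], window[["y_hi"]])
  fc[hit, ]
}

#' Features visible in a viewport under the LOD policy
#'
#' A feature is returned iff its geometry intersects the viewport window
#' and its on-screen size at the viewport's zoom passes the LOD policy:
#' taxon rectangles need `min_rect_height_px` of height; edges and leaf
#' anchors have no size threshold. The `show_label` flag obeys
#' `min_leaf_pitch_px` (leaf labels) and `min_bracket_height_px`
#' (taxon-rectangle labels); it never flips from shown to hidden as zoom
#' increases.
#'
#' @inheritParams window_query
#' @param viewport A [viewport()].
#' @param lod A [lod_policy()].
#' @return Matching features with columns `height_px` and `show_label`
#'   appended.
#' @export
visible_features <- function(index, viewport, lod = lod_policy()) {
  stopifnot(inherits(viewport, "phylomap_viewport"))
  tr <- world_transform(index$extent, viewport$zoom, index$tile_size,
                        index$pad_frac)
  feats <- window_query(index, viewport$window)
  height_px <- (feats$y_hi - feats$y_lo) * tr$scale_y
  keep <- feats$kind != "taxon_rect" | height_px >= lod$min_rect_height_px
  feats <- feats[keep, ]
  height_px <- height_px[keep]
  leaf_pitch <- tr$scale_y   # leaf spacing is 1.0 world units
  feats$height_px <- height_px
  feats$show_label <- ifelse(
    feats$kind == "leaf_label", leaf_pitch >= lod$min_leaf_pitch_px,
    ifelse(feats$kind == "taxon_rect", height_px >= lod$min_bracket_height_px,
           FALSE)
  )
  feats
}

#' Default maximum zoom for a layout
#'
#' The smallest zoom at which the leaf pitch reaches `target_pitch_px`
#' (so individual sequences are comfortably separated), capped at
#' `z_cap`.
#'
#' @inheritParams world_transform
#' @param target_pitch_px Desired pixels between adjacent leaves.
#' @param z_cap Hard upper bound on the zoom level.
#' @return An integer zoom level.
#' @export
default_z_max <- function(extent, tile_size = 256L, pad_frac = 0.02,
                          target_pitch_px = 16, z_cap = 18L) {
  for (z in 0:z_cap) {
    tr <- world_transform(extent, z, tile_size, pad_frac)
    if (tr$scale_y >= target_pitch_px) return(z)
  }
  z_cap
}
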