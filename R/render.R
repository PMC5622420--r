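# Raster tile rendering. All drawing is done in global pixel coordinates
# (gp = floor(world * scale)) and then offset into the tile, so features
# straddling tile borders are clipped identically on both sides and
# adjacent tiles butt seamlessly. No anti-aliasing: edges are 1-px lines.

# 5x7 bitmap font, one integer per glyph row (5 bits, MSB = leftmost).
# Covers A-Z, 0-9 and basic punctuation; lowercase is mapped to uppercase,
# anything unknown renders as a filled box.
font5x7_ <- local({
  g <- list(
    A = c(14,17,17,31,17,17,17), B = c(30,17,17,30,17,17,30),
    C = c(14,17,16,16,16,17,14), D = c(30,17,17,17,17,17,30),
    E = c(31,16,16,30,16,16,31), F = c(31,16,16,30,16,16,16),
    G = c(14,17,16,23,17,17,14), H = c(17,17,17,31,17,17,17),
    I = c(14,4,4,4,4,4,14),      J = c(7,2,2,2,2,18,12),
    K = c(17,18,20,24,20,18,17), L = c(16,16,16,16,16,16,31),
    M = c(17,27,21,21,17,17,17), N = c(17,25,21,19,17,17,17),
    O = c(14,17,17,17,17,17,14), P = c(30,17,17,30,16,16,16),
    Q = c(14,17,17,17,21,18,13), R = c(30,17,17,30,20,18,17),
    S = c(15,16,16,14,1,1,30),   T = c(31,4,4,4,4,4,4),
    U = c(17,17,17,17,17,17,14), V = c(17,17,17,17,17,10,4),
    W = c(17,17,17,21,21,21,10), X = c(17,17,10,4,10,17,17),
    Y = c(17,17,10,4,4,4,4),     Z = c(31,1,2,4,8,16,31),
    `0` = c(14,17,19,21,25,17,14), `1` = c(4,12,4,4,4,4,14),
    `2` = c(14,17,1,2,4,8,31),     `3` = c(31,2,4,2,1,17,14),
    `4` = c(2,6,10,18,31,2,2),     `5` = c(31,16,30,1,1,17,14),
    `6` = c(6,8,16,30,17,17,14),   `7` = c(31,1,2,4,8,8,8),
    `8` = c(14,17,17,14,17,17,14), `9` = c(14,17,17,15,1,2,12),
    `.` = c(0,0,0,0,0,12,12),  `-` = c(0,0,0,14,0,0,0),
    `_` = c(0,0,0,0,0,0,31),   ` ` = c(0,0,0,0,0,0,0),
    `|` = c(4,4,4,4,4,4,4)
  )
  unknown <- c(31,31,31,31,31,31,31)
  # precompute 7x5 logical matrices
  mats <- lapply(g, function(rows) {
    t(vapply(rows, function(r) as.logical(bitwAnd(r, c(16L, 8L, 4L, 2L, 1L))),
             logical(5)))
  })
  list(mats = mats, unknown = t(vapply(unknown, function(r)
    as.logical(bitwAnd(r, c(16L, 8L, 4L, 2L, 1L))), logical(5))))
})

glyph_mat_ <- function(ch) {
  m <- font5x7_$mats[[toupper(ch)]]
  if (is.null(m)) font5x7_$unknown else m
}

hex_to_rgb_ <- function(hex) {
  c(strtoi(substr(hex, 2, 3), 16L),
    strtoi(substr(hex, 4, 5), 16L),
    strtoi(substr(hex, 6, 7), 16L)) / 255
}

# Composite a constant colour (straight alpha) over a region of the RGBA
# canvas, in place. rows/cols are 1-based local pixel ranges, pre-clipped.
blend_rect_ <- function(img, rows, cols, rgb, alpha) {
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  da <- img[rows, cols, 4]
  oa <- alpha + da * (1 - alpha)
  for (ch in 1:3) {
    dc <- img[rows, cols, ch]
    img[rows, cols, ch] <- (rgb[ch] * alpha + dc * da * (1 - alpha)) / pmax(oa, 1e-12)
  }
  img[rows, cols, 4] <- oa
  img
}

#' Render one raster tile
#'
#' Draws, in order: taxon rectangles (rank colour, 25% opacity, subject
#' to the `min_rect_height_px` LOD rule), edge segments (opaque 1-px
#' lines), and sequence labels (bitmap text, only when the leaf pitch at
#' this zoom reaches `min_leaf_pitch_px`). The background is fully
#' transparent. Output is deterministic for fixed inputs, and features
#' crossing tile borders are clipped consistently so adjacent tiles butt
#' seamlessly.
#'
#' @inheritParams window_query
#' @param z,tx,ty Tile address; out-of-range addresses raise a
#'   `phylomap_address_error`.
#' @param lod A [lod_policy()].
#' @param edge_color,label_color Hex colours for edges and text.
#' @return A `tile_size x tile_size x 4` numeric array (RGBA in [0, 1]).
#' @examples
#' tr <- generate_fixture(30, seed = 1)
#' lay <- compute_layout(tr)
#' idx <- build_index(lay, compute_taxon_rects(tr, lay))
#' tile <- render_tile(idx, 0, 0, 0)
#' dim(tile)
#' @export
render_tile <- function(index, z, tx, ty, lod = lod_policy(),
                        edge_color = "#222222", label_color = "#000000") {
  stopifnot(inherits(index, "phylomap_index"))
  tile_address(z, tx, ty)
  ts <- index$tile_size
  tr <- world_transform(index$extent, z, ts, index$pad_frac)
  s <- tr$scale_x
  win <- tile_window(tr, z, tx, ty)

  fs <- max(1L, as.integer(floor(lod$label_font_px / 7)))
  draw_labels <- tr$scale_y >= lod$min_leaf_pitch_px
  # labels extend right of their anchor; widen the query window so a
  # label anchored in a neighbouring tile still paints into this one
  slop <- if (draw_labels) (index$max_label_px %||% 400) * fs / s else 0
  qwin <- c(x_lo = win[["x_lo"]] - slop, x_hi = win[["x_hi"]],
            y_lo = win[["y_lo"]] - slop, y_hi = win[["y_hi"]] + slop)
  feats <- window_query(index, qwin)

  img <- array(0, dim = c(ts, ts, 4))
  px0 <- tx * ts   # global pixel offset of this tile
  py0 <- ty * ts

  clipc <- function(g) pmin(pmax(g - px0 + 1L, 1L), ts)
  clipr <- function(g) pmin(pmax(g - py0 + 1L, 1L), ts)

  # 1. taxon rectangles
  rects <- feats[feats$kind == "taxon_rect", ]
  if (nrow(rects)) {
    keep <- (rects$y_hi - rects$y_lo) * s >= lod$min_rect_height_px
    rects <- rects[keep, ]
    for (i in seq_len(nrow(rects))) {
      gx <- floor(c(rects$x_lo[i], rects$x_hi[i]) * s)
      gy <- floor(c(rects$y_lo[i], rects$y_hi[i]) * s)
      if (gx[2] < px0 || gx[1] > px0 + ts - 1 || gy[2] < py0 || gy[1] > py0 + ts - 1) next
      cols <- clipc(gx[1]):clipc(gx[2])
      rows <- clipr(gy[1]):clipr(gy[2])
      img <- blend_rect_(img, rows, cols, hex_to_rgb_(rects$color[i]), 0.25)
    }
  }

  # 2. edges (opaque, 1 px)
  ec <- hex_to_rgb_(edge_color)
  edges <- feats[feats$kind %in% c("edge_h", "edge_v"), ]
  if (nrow(edges)) {
    gx0 <- floor(edges$x_lo * s); gx1 <- floor(edges$x_hi * s)
    gy0 <- floor(edges$y_lo * s); gy1 <- floor(edges$y_hi * s)
    for (i in seq_len(nrow(edges))) {
      if (gx1[i] < px0 || gx0[i] > px0 + ts - 1 ||
          gy1[i] < py0 || gy0[i] > py0 + ts - 1) next
      cols <- clipc(gx0[i]):clipc(gx1[i])
      rows <- clipr(gy0[i]):clipr(gy1[i])
      img[rows, cols, 1] <- ec[1]
      img[rows, cols, 2] <- ec[2]
      img[rows, cols, 3] <- ec[3]
      img[rows, cols, 4] <- 1
    }
  }

  # 3. sequence labels
  if (draw_labels) {
    lc <- hex_to_rgb_(label_color)
    labs <- feats[feats$kind == "leaf_label", ]
    for (i in seq_len(nrow(labs))) {
      gx <- floor(labs$x_lo[i] * s) + 3L
      gy <- floor(labs$y_lo[i] * s) - 3L * fs
      img <- draw_text_(img, labs$name[i], gx, gy, fs, lc, px0, py0, ts)
    }
  }
  img
}

# Draw text whose glyph origin (top-left) is at global pixel (gx, gy).
draw_text_ <- function(img, text, gx, gy, fs, rgb, px0, py0, ts) {
  if (is.na(text) || !nzchar(text)) return(img)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  x <- gx
  for (ch in chars) {
    m <- glyph_mat_(ch)
    # glyph cell: 5 cols + 1 spacing, 7 rows, scaled by fs
    if (x + 5L * fs >= px0 && x <= px0 + ts - 1L &&
        gy + 7L * fs >= py0 && gy <= py0 + ts - 1L) {
      on <- which(m, arr.ind = TRUE)
      for (k in seq_len(nrow(on))) {
        r0 <- gy + (on[k, 1] - 1L) * fs
        c0 <- x + (on[k, 2] - 1L) * fs
        rows <- (r0):(r0 + fs - 1L)
        cols <- (c0):(c0 + fs - 1L)
        rows <- rows[rows >= py0 & rows <= py0 + ts - 1L] - py0 + 1L
        cols <- cols[cols >= px0 & cols <= px0 + ts - 1L] - px0 + 1L
        if (length(rows) && length(cols)) {
          img[rows, cols, 1] <- rgb[1]
          img[rows, cols, 2] <- rgb[2]
          img[rows, cols, 3] <- rgb[3]
          img[rows, cols, 4] <- 1
        }
      }
    }
    x <- x + 6L * fs
  }
  img
}

#' Build the tile pyramid on disk
#'
#' Renders every tile from zoom 0 to `z_max` whose window intersects the
#' occupied extent, writing non-empty tiles as `{z}/{tx}/{ty}.png` under
#' `out_dir` plus a `manifest.json` recording the extent, zoom range,
#' tile size, configuration hash, and the full candidate tile list with a
#' `written` flag (fully transparent tiles are skipped but recorded).
#' Two builds from the same inputs are byte-identical.
#'
#' @inheritParams render_tile
#' @param z_max Deepest zoom level (default [default_z_max()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a `phylomap_pyramid` list: `n_written`, `n_candidates`,
#'   `z_max`, `out_dir`, `manifest` (the parsed manifest).
#' @export
build_pyramid <- function(index, z_max = NULL, out_dir, lod = lod_policy()) {
  stopifnot(inherits(index, "phylomap_index"))
  if (is.null(z_max)) {
    z_max <- default_z_max(index$extent, index$tile_size, index$pad_frac)
  }
  if (!is_count_(z_max) || z_max < 0) abort_config("z_max must be a non-negative integer")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io(paste0("cannot create tile directory ", out_dir))
  ext <- index$extent
  tiles <- list()
  n_written <- 0L
  for (z in 0:z_max) {
    tr <- world_transform(ext, z, index$tile_size, index$pad_frac)
    side <- tr$padded_side / 2^z
    c0 <- max(0L, floor(ext[["x_min"]] / side))
    c1 <- min(2^z - 1L, floor(ext[["x_max"]] / side))
    r0 <- max(0L, floor(ext[["y_min"]] / side))
    r1 <- min(2^z - 1L, floor(ext[["y_max"]] / side))
    for (tx in c0:c1) {
      for (ty in r0:r1) {
        img <- render_tile(index, z, tx, ty, lod)
        written <- any(img[, , 4] > 0)
        if (written) {
          d <- file.path(out_dir, z, tx)
          dir.create(d, recursive = TRUE, showWarnings = FALSE)
          png::writePNG(img, file.path(d, paste0(ty, ".png")))
          n_written <- n_written + 1L
        }
        tiles[[length(tiles) + 1L]] <- list(z = z, tx = tx, ty = ty,
                                            written = written)
      }
    }
  }
  tile_tbl <- list_rbind(map(tiles, as_tibble))
  cfg <- list(tile_size = index$tile_size, pad_frac = index$pad_frac,
              z_max = z_max, lod = unclass(lod))
  manifest <- list(
    extent = as.list(ext),
    zoom_range = c(0L, as.integer(z_max)),
    tile_size = index$tile_size,
    pad_frac = index$pad_frac,
    config_hash = md5_string_(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)),
    n_candidates = nrow(tile_tbl),
    n_written = n_written,
    tiles = tile_tbl
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(list(
    n_written = n_written, n_candidates = nrow(tile_tbl), z_max = z_max,
    out_dir = out_dir, manifest = manifest
  ), class = "phylomap_pyramid"))
}

#' @export
print.phylomap_pyramid <- function(x, ...) {
  cat(sprintf("<phylomap_pyramid> %d/%d tiles written, zoom 0..%d, at %s\n",
              x$n_written, x$n_candidates, x$z_max, x$out_dir))
  invisible(x)
}
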