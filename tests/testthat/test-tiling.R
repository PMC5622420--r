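test_that("tile windows partition the padded square exactly", {
  st <- cached_stack(120, seed = 2)
  tr <- world_transform(st$layout$extent, 0)
  for (z in 0:3) {
    side <- tr$padded_side / 2^z
    # edges shared exactly between neighbours, union covers the square
    for (t in 0:(2^z - 1)) {
      w <- tile_window(tr, z, t, t)
      expect_identical(w[["x_lo"]], t * side)
      expect_identical(w[["x_hi"]], (t + 1) * side)
    }
    w_last <- tile_window(tr, z, 2^z - 1, 2^z - 1)
    expect_equal(w_last[["x_hi"]], tr$padded_side, tolerance = 1e-12)
    w_first <- tile_window(tr, z, 0, 0)
    expect_identical(w_first[["x_lo"]], 0)
  }
  expect_error(tile_window(tr, 2, 4, 0), class = "phylomap_address_error")
  expect_error(tile_window(tr, 2, 0, -1), class = "phylomap_address_error")
})

test_that("scale doubles with zoom and maps the world onto the tile grid", {
  st <- cached_stack(80, seed = 3)
  ext <- st$layout$extent
  for (z in 0:6) {
    tr <- world_transform(ext, z)
    expect_equal(tr$scale_x, tr$scale_y)
    expect_equal(tr$scale_x * tr$padded_side, 2^z * tr$tile_size)
  }
  expect_equal(world_transform(ext, 5)$scale_x / world_transform(ext, 4)$scale_x, 2)
})

test_that("window queries equal the linear-scan oracle", {
  withr::local_seed(42)
  for (seed in c(1, 2)) {
    st <- cached_stack(300, seed)
    idx <- build_index(st$layout, st$rects)
    for (k in 1:100) {
      w <- random_window(st$layout$extent)
      got <- window_query(idx, w)$feature_id
      expect_identical(sort(got), sort(oracle_window_scan(idx$features, w)))
    }
  }
})

test_that("full-extent windows return everything; disjoint windows nothing", {
  st <- cached_stack(150, seed = 5)
  idx <- build_index(st$layout, st$rects)
  ext <- st$layout$extent
  all_w <- c(x_lo = -1, x_hi = ext[["x_max"]] + 1,
             y_lo = -1, y_hi = ext[["y_max"]] + 1)
  expect_equal(nrow(window_query(idx, all_w)), nrow(idx$features))
  far <- c(x_lo = ext[["x_max"]] + 10, x_hi = ext[["x_max"]] + 20,
           y_lo = ext[["y_max"]] + 10, y_hi = ext[["y_max"]] + 20)
  expect_equal(nrow(window_query(idx, far)), 0L)
})

test_that("label visibility obeys the leaf-pitch threshold and is monotone in zoom", {
  st <- cached_stack(1000, seed = 7)
  idx <- build_index(st$layout, st$rects)
  ext <- st$layout$extent
  win <- c(x_lo = 0, x_hi = ext[["x_max"]], y_lo = 100, y_hi = 160)
  lod <- lod_policy()
  prev_shown <- NULL
  prev_visible <- NULL
  for (z in 0:14) {
    vp <- viewport(win[["x_lo"]], win[["x_hi"]], win[["y_lo"]], win[["y_hi"]], z)
    tr <- world_transform(ext, z, idx$tile_size, idx$pad_frac)
    vf <- visible_features(idx, vp, lod)
    labs <- vf[vf$kind == "leaf_label", ]
    if (tr$scale_y < lod$min_leaf_pitch_px) {
      expect_false(any(labs$show_label))
    } else {
      expect_true(all(labs$show_label))
    }
    shown <- labs$ref[labs$show_label]
    visible <- vf$feature_id
    if (!is.null(prev_shown)) {
      expect_true(all(prev_shown %in% shown))       # labels never disappear
      expect_true(all(prev_visible %in% visible))   # zoom coherence (pre-LOD geometry fixed)
    }
    prev_shown <- shown
    prev_visible <- visible
  }
})

test_that("taxon rectangles are culled below the minimum pixel height", {
  st <- cached_stack(1000, seed = 7)
  idx <- build_index(st$layout, st$rects)
  ext <- st$layout$extent
  vp0 <- viewport(0, ext[["x_max"]], 0, ext[["y_max"]], 0)
  tr0 <- world_transform(ext, 0, idx$tile_size, idx$pad_frac)
  vf0 <- visible_features(idx, vp0, lod_policy())
  rect_rows <- idx$features[idx$features$kind == "taxon_rect", ]
  small <- (rect_rows$y_hi - rect_rows$y_lo) * tr0$scale_y < 2
  kept <- rect_rows$feature_id %in% vf0$feature_id
  expect_identical(kept, !small)
})

test_that("tiles outside the occupied extent are fully transparent", {
  st <- cached_stack(200, seed = 8)
  idx <- build_index(st$layout, st$rects)
  # the tree occupies a thin left column of the padded square, so the
  # top-right tile at z=2 is empty
  tile <- render_tile(idx, 2, 3, 0)
  expect_equal(sum(tile[, , 4]), 0)
})

test_that("tile rendering is deterministic", {
  st <- cached_stack(200, seed = 8)
  idx <- build_index(st$layout, st$rects)
  a <- render_tile(idx, 0, 0, 0)
  b <- render_tile(idx, 0, 0, 0)
  expect_identical(a, b)
  expect_equal(dim(a), c(256, 256, 4))
})

test_that("features crossing a tile border are clipped consistently", {
  st <- cached_stack(300, seed = 9)
  idx <- build_index(st$layout, st$rects)
  z <- 3L
  tr <- world_transform(st$layout$extent, z, idx$tile_size, idx$pad_frac)
  s <- tr$scale_x
  t00 <- render_tile(idx, z, 0, 0)
  t01 <- render_tile(idx, z, 0, 1)
  # every vertical connector whose world span crosses the seam between
  # tile rows 0 and 1 must light the same pixel column on both sides
  v <- idx$features[idx$features$kind == "edge_v", ]
  crossing <- v[floor(v$y_lo * s) < 256 & floor(v$y_hi * s) >= 256 &
                  floor(v$x_lo * s) < 256, ]
  expect_gt(nrow(crossing), 0)
  for (i in seq_len(nrow(crossing))) {
    col <- floor(crossing$x_lo[i] * s) + 1L
    expect_equal(t00[256, col, 4], 1)
    expect_equal(t01[1, col, 4], 1)
  }
})

test_that("pyramid counts, manifest candidates, and determinism", {
  st <- cached_stack(500, seed = 11)
  idx <- build_index(st$layout, st$rects)
  d0 <- withr::local_tempdir()
  p0 <- build_pyramid(idx, 0, file.path(d0, "z0"))
  expect_equal(p0$n_candidates, 1L)
  expect_equal(p0$n_written, 1L)

  p2 <- build_pyramid(idx, 2, file.path(d0, "z2"))
  expect_lte(p2$n_candidates, 21L)

  p3a <- build_pyramid(idx, 3, file.path(d0, "a"))
  p3b <- build_pyramid(idx, 3, file.path(d0, "b"))
  fa <- sort(list.files(file.path(d0, "a"), recursive = TRUE))
  fb <- sort(list.files(file.path(d0, "b"), recursive = TRUE))
  expect_identical(fa, fb)
  for (f in fa) {
    expect_identical(readBin(file.path(d0, "a", f), "raw", 5e6),
                     readBin(file.path(d0, "b", f), "raw", 5e6))
  }

  # manifest candidate set == addresses whose window intersects the
  # occupied extent
  man <- jsonlite::fromJSON(file.path(d0, "z2", "manifest.json"))
  tiles <- man$tiles
  ext <- st$layout$extent
  tr <- world_transform(ext, 0, idx$tile_size, idx$pad_frac)
  expected <- list()
  for (z in 0:2) {
    side <- tr$padded_side / 2^z
    for (tx in 0:(2^z - 1)) for (ty in 0:(2^z - 1)) {
      w <- c(tx * side, (tx + 1) * side, ty * side, (ty + 1) * side)
      if (w[1] <= ext[["x_max"]] && w[2] >= ext[["x_min"]] &&
          w[3] <= ext[["y_max"]] && w[4] >= ext[["y_min"]]) {
        expected[[length(expected) + 1L]] <- c(z, tx, ty)
      }
    }
  }
  got <- sprintf("%d/%d/%d", tiles$z, tiles$tx, tiles$ty)
  want <- vapply(expected, function(a) sprintf("%d/%d/%d", a[1], a[2], a[3]), "")
  expect_setequal(got, want)
})

test_that("stitching zoom-2 tiles reproduces the zoom-0 thumbnail", {
  st <- cached_stack(500, seed = 11)
  idx <- build_index(st$layout, st$rects)
  z0 <- render_tile(idx, 0, 0, 0)
  big <- array(0, dim = c(1024, 1024, 4))
  for (tx in 0:3) for (ty in 0:3) {
    big[ty * 256 + (1:256), tx * 256 + (1:256), ] <- render_tile(idx, 2, tx, ty)
  }
  ds <- array(0, dim = c(256, 256, 4))
  for (ch in 1:4) {
    m <- big[, , ch]
    acc <- matrix(0, 256, 256)
    for (i in 0:3) for (j in 0:3) {
      acc <- acc + m[seq(1 + i, 1024, 4), seq(1 + j, 1024, 4)]
    }
    ds[, , ch] <- acc / 16
  }
  for (ch in 1:4) {
    expect_lt(mean(abs(ds[, , ch] - z0[, , ch])) * 255, 5)
  }
})

test_that("default z_max reaches a readable leaf pitch", {
  st <- cached_stack(500, seed = 11)
  z <- default_z_max(st$layout$extent)
  tr <- world_transform(st$layout$extent, z)
  expect_gte(tr$scale_y, 16)
  if (z > 0) {
    expect_lt(world_transform(st$layout$extent, z - 1)$scale_y, 16)
  }
})
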