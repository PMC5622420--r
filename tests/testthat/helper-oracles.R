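# Shared fixtures (cached per test run) and independent brute-force
# oracles used to check the package's fast paths.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(n_leaves, seed) {
  key <- paste0("n", n_leaves, "_s", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_fixture(n_leaves, seed = seed)
  }
  .fixture_cache[[key]]
}

cached_stack <- function(n_leaves, seed) {
  key <- paste0("stack_n", n_leaves, "_s", seed)
  if (is.null(.fixture_cache[[key]])) {
    tree <- cached_fixture(n_leaves, seed)
    lay <- compute_layout(tree)
    rects <- compute_taxon_rects(tree, lay)
    .fixture_cache[[key]] <- list(tree = tree, layout = lay, rects = rects)
  }
  .fixture_cache[[key]]
}

# x oracle: per-node root-path branch-length sum by explicit parent walk.
oracle_node_x <- function(tree) {
  par <- tree$nodes$parent
  bl <- tree$nodes$branch_length
  vapply(tree$nodes$node, function(v) {
    s <- 0
    while (!is.na(par[v])) {
      s <- s + bl[v]
      v <- par[v]
    }
    s
  }, numeric(1))
}

# Clade membership: breadth-first expansion from `anc` over a child list
# built directly from the parent vector.
oracle_clade_nodes <- function(tree, anc) {
  par <- tree$nodes$parent
  kids_of <- split(tree$nodes$node[!is.na(par)], par[!is.na(par)])
  in_clade <- logical(nrow(tree$nodes))
  queue <- anc
  while (length(queue)) {
    in_clade[queue] <- TRUE
    queue <- unlist(kids_of[as.character(queue)], use.names = FALSE)
  }
  in_clade
}

# Rect oracle: exhaustive min/max over the clade's nodes and edge
# segments (including the clade root's incoming horizontal edge).
oracle_taxon_rect <- function(tree, layout, taxon_id) {
  par <- tree$nodes$parent
  x <- layout$nodes$x
  y <- layout$nodes$y
  in_clade <- oracle_clade_nodes(tree, taxon_id)
  members <- tree$nodes$node[in_clade]
  leaves <- members[members <= tree$n_leaves]
  p <- par[members]
  # own x plus the start of each member's incoming edge (0 at the root)
  xs <- c(x[members], ifelse(is.na(p), 0, x[ifelse(is.na(p), 1L, p)]))
  list(
    x_lo = min(xs), x_hi = max(xs),
    y_lo = min(y[leaves]), y_hi = max(y[leaves]),
    sequence_count = length(leaves)
  )
}

# Window-query oracle: plain linear scan with closed-interval overlap.
oracle_window_scan <- function(features, window) {
  hit <- features$x_lo <= window[["x_hi"]] & window[["x_lo"]] <= features$x_hi &
    features$y_lo <= window[["y_hi"]] & window[["y_lo"]] <= features$y_hi
  features$feature_id[hit]
}

random_window <- function(extent, margin = 0.2) {
  w <- extent[["x_max"]] - extent[["x_min"]]
  h <- extent[["y_max"]] - extent[["y_min"]]
  x0 <- runif(1, extent[["x_min"]] - margin * w, extent[["x_max"]])
  y0 <- runif(1, extent[["y_min"]] - margin * h, extent[["y_max"]])
  c(x_lo = x0, x_hi = x0 + runif(1, 1e-6, w * (1 + margin)),
    y_lo = y0, y_hi = y0 + runif(1, 1e-6, h * (1 + margin)))
}

# Write a minimal config file pointing into `dir`; returns its path.
write_test_config <- function(dir, extra = character()) {
  cfg <- file.path(dir, "phylomap.ini")
  writeLines(c(
    "[paths]",
    "tree = fixture.nwk",
    "metadata = fixture.tsv",
    "build_dir = build",
    "reports = reports.jsonl",
    "[tiles]",
    "tile_size = 256",
    "z_max = 3",
    extra
  ), cfg)
  cfg
}

expect_same_hits <- function(result, expected_ids) {
  expect_setequal(result$hits$id, as.character(expected_ids))
}
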