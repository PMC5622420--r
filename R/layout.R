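#' Compute the rectangular-phylogram layout in world coordinates
#'
#' World coordinates follow the web-map convention for tree browsers:
#' x is the root-path branch-length sum (branch-length units, root at 0,
#' growing rightward), y is the leaf index (leaf pitch 1.0, leaf k at
#' y = k in tree leaf order, growing downward). Internal nodes sit at the
#' midpoint of their first and last child's y. Each non-root node owns one
#' horizontal edge segment (parent x to own x at its y); each internal
#' node owns one vertical connector (at its x, spanning first to last
#' child y). Making y independent of branch lengths keeps vertical
#' geometry stable under re-estimation of lengths, while the x axis stays
#' meaningful for a scale bar.
#'
#' @param tree A `phylomap_tree` from [read_tree_map()] or
#'   [generate_fixture()].
#' @return A `phylomap_layout` list: `nodes` (tibble: `node`, `parent`,
#'   `is_leaf`, `label`, `accession`, `full_name`, `leaf_index`, `x`,
#'   `y`), `edges` (tibble: `node`, `kind` `"h"`/`"v"`, `x0`, `x1`, `y0`,
#'   `y1`), `extent` (named numeric `x_min`, `x_max`, `y_min`, `y_max`;
#'   `x_min = y_min = 0`, `y_max = n_leaves - 1`), `n_leaves`.
#' @examples
#' lay <- compute_layout(generate_fixture(20, seed = 1))
#' lay$extent
#' @export
compute_layout <- function(tree) {
  stopifnot(inherits(tree, "phylomap_tree"))
  phy <- tree$phylo
  n_tip <- tree$n_leaves
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L

  x <- ape::node.depth.edgelength(phy)

  # first/last child per internal node, in cladewise child order
  epar <- phy$edge[, 1]
  echi <- phy$edge[, 2]
  first_child <- integer(n_node)
  last_child <- integer(n_node)
  first_child[epar[!duplicated(epar)]] <- echi[!duplicated(epar)]
  revd <- !duplicated(epar, fromLast = TRUE)
  last_child[epar[revd]] <- echi[revd]

  y <- numeric(n_node)
  y[seq_len(n_tip)] <- seq_len(n_tip) - 1
  # children precede parents in reverse cladewise-appearance order
  internals_pre <- unique(epar)   # preorder appearance
  for (v in rev(internals_pre)) {
    y[v] <- (y[first_child[v]] + y[last_child[v]]) / 2
  }

  parent <- rep(NA_integer_, n_node)
  parent[echi] <- epar

  nodes <- tibble(
    node = seq_len(n_node),
    parent = parent,
    is_leaf = seq_len(n_node) <= n_tip,
    label = tree$nodes$label,
    accession = c(tree$sequences$accession, rep(NA_character_, phy$Nnode)),
    full_name = c(tree$sequences$full_name, rep(NA_character_, phy$Nnode)),
    leaf_index = c(seq_len(n_tip) - 1L, rep(NA_integer_, phy$Nnode)),
    x = x,
    y = y
  )

  h <- tibble(
    node = echi, kind = "h",
    x0 = x[epar], x1 = x[echi],
    y0 = y[echi], y1 = y[echi]
  )
  ints <- internals_pre
  v_edges <- tibble(
    node = ints, kind = "v",
    x0 = x[ints], x1 = x[ints],
    y0 = y[first_child[ints]], y1 = y[last_child[ints]]
  )
  edges <- bind_rows(h, v_edges)

  structure(list(
    nodes = nodes,
    edges = edges,
    extent = c(x_min = 0, x_max = max(x), y_min = 0, y_max = n_tip - 1),
    n_leaves = n_tip
  ), class = "phylomap_layout")
}

#' Bounding rectangles of annotated taxa, coloured by rank
#'
#' One rectangle per taxonomic annotation: the y-interval spans the first
#' to last leaf index of the taxon's clade; the x-interval is the tight
#' x-range over every node and edge segment of the clade, including the
#' clade root's incoming horizontal edge (so a rectangle visually encloses
#' everything drawn for the group). `sequence_count` is the number of
#' leaves in the clade. Rectangles nest in y along the annotation
#' hierarchy.
#'
#' @inheritParams compute_layout
#' @param layout The layout computed from `tree` by [compute_layout()].
#' @param palette Named character vector mapping each rank present in the
#'   tree to a `#RRGGBB` colour; a rank without a colour raises a
#'   `phylomap_config_error`.
#' @return A tibble, one row per annotated taxon, sorted by rank (most
#'   generic first) then `y_lo`: `taxon_id`, `taxon_name`, `rank`,
#'   `rank_index`, `parent_taxon`, `path`, `x_lo`, `x_hi`, `y_lo`,
#'   `y_hi`, `sequence_count`, `color`.
#' @examples
#' tr <- generate_fixture(20, seed = 1)
#' compute_taxon_rects(tr, compute_layout(tr))
#' @export
compute_taxon_rects <- function(tree, layout,
                                palette = default_palette(tree$rank_order)) {
  stopifnot(inherits(tree, "phylomap_tree"), inherits(layout, "phylomap_layout"))
  taxa <- tree$taxa
  if (nrow(taxa) == 0L) {
    return(tibble(
      taxon_id = integer(), taxon_name = character(), rank = character(),
      rank_index = integer(), parent_taxon = integer(), path = character(),
      x_lo = numeric(), x_hi = numeric(), y_lo = numeric(), y_hi = numeric(),
      sequence_count = integer(), color = character()
    ))
  }
  check_palette_(palette, unique(taxa$rank))
  phy <- tree$phylo
  n_tip <- tree$n_leaves
  n_node <- n_tip + phy$Nnode
  x <- layout$nodes$x
  y <- layout$nodes$y

  # subtree aggregates by one reverse-cladewise sweep (children first)
  min_leaf <- rep(Inf, n_node)
  max_leaf <- rep(-Inf, n_node)
  n_leaf <- integer(n_node)
  max_x <- x
  min_leaf[seq_len(n_tip)] <- y[seq_len(n_tip)]
  max_leaf[seq_len(n_tip)] <- y[seq_len(n_tip)]
  n_leaf[seq_len(n_tip)] <- 1L
  epar <- phy$edge[, 1]
  echi <- phy$edge[, 2]
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- epar[e]; v <- echi[e]
    if (min_leaf[v] < min_leaf[p]) min_leaf[p] <- min_leaf[v]
    if (max_leaf[v] > max_leaf[p]) max_leaf[p] <- max_leaf[v]
    n_leaf[p] <- n_leaf[p] + n_leaf[v]
    if (max_x[v] > max_x[p]) max_x[p] <- max_x[v]
  }

  parent <- rep(NA_integer_, n_node)
  parent[echi] <- epar
  t_id <- taxa$taxon_id
  tp <- parent[t_id]
  x_lo <- numeric(length(t_id))          # root taxon: incoming edge is at x = 0
  x_lo[!is.na(tp)] <- x[tp[!is.na(tp)]]

  rects <- tibble(
    taxon_id = t_id,
    taxon_name = taxa$taxon_name,
    rank = taxa$rank,
    rank_index = taxa$rank_index,
    parent_taxon = taxa$parent_taxon,
    path = taxa$path,
    x_lo = x_lo,
    x_hi = max_x[t_id],
    y_lo = min_leaf[t_id],
    y_hi = max_leaf[t_id],
    sequence_count = n_leaf[t_id],
    color = unname(palette[taxa$rank])
  )
  arrange(rects, .data$rank_index, .data$y_lo)
}

#' @export
print.phylomap_layout <- function(x, ...) {
  cat(sprintf(
    "<phylomap_layout> %d leaves; extent x [0, %.6g], y [0, %d]\n",
    x$n_leaves, x$extent[["x_max"]], as.integer(x$extent[["y_max"]])
  ))
  invisible(x)
}
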