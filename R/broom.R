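#' Tidy and summary methods
#'
#' `tidy()` returns the row-per-observation view of each phylomap object
#' (nodes for a layout, hits for a search result, sequence records for a
#' tree, candidate tiles for a pyramid); `glance()` returns a one-row
#' summary.
#'
#' @param x A phylomap object.
#' @param ... Unused.
#' @return A tibble.
#' @name phylomap-tidiers
NULL

#' @rdname phylomap-tidiers
#' @export
tidy.phylomap_tree <- function(x, ...) {
  mutate(x$sequences, leaf_index = row_number() - 1L)
}

#' @rdname phylomap-tidiers
#' @export
glance.phylomap_tree <- function(x, ...) {
  tibble(
    n_leaves = x$n_leaves,
    n_internal = x$phylo$Nnode,
    n_taxa = nrow(x$taxa),
    n_ranks = length(x$rank_order),
    total_branch_length = sum(x$phylo$edge.length)
  )
}

#' @rdname phylomap-tidiers
#' @export
tidy.phylomap_layout <- function(x, ...) x$nodes

#' @rdname phylomap-tidiers
#' @export
glance.phylomap_layout <- function(x, ...) {
  tibble(
    n_leaves = x$n_leaves,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    x_max = x$extent[["x_max"]],
    y_max = x$extent[["y_max"]]
  )
}

#' @rdname phylomap-tidiers
#' @export
tidy.phylomap_result <- function(x, ...) x$hits

#' @rdname phylomap-tidiers
#' @export
glance.phylomap_result <- function(x, ...) {
  tibble(kind = x$kind, n_hits = nrow(x$hits), cursor = x$cursor)
}

#' @rdname phylomap-tidiers
#' @export
tidy.phylomap_pyramid <- function(x, ...) as_tibble(x$manifest$tiles)

#' @rdname phylomap-tidiers
#' @export
glance.phylomap_pyramid <- function(x, ...) {
  tibble(n_written = x$n_written, n_candidates = x$n_candidates,
         z_max = x$z_max)
}

#' Plot a tree layout as a rectangular phylogram
#'
#' Draws the world-coordinate geometry with ggplot2: edge segments,
#' optional rank-coloured taxon rectangles, and optional search-hit
#' markers (all hits as dots, the current hit circled). The y axis is
#' reversed so leaf 0 is at the top, matching tile pixel orientation.
#'
#' @param object A `phylomap_layout`.
#' @param rects Optional taxon rectangles from [compute_taxon_rects()].
#' @param hits Optional `phylomap_result` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phylomap_layout <- function(object, rects = NULL, hits = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(rects) && nrow(rects)) {
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$x_lo, xmax = .data$x_hi,
                   ymin = .data$y_lo, ymax = .data$y_hi, fill = .data$rank),
      alpha = 0.25
    ) + ggplot2::scale_fill_manual(
      values = setNames(unique(rects$color), unique(rects$rank))
    )
  }
  p <- p + ggplot2::geom_segment(
    data = object$edges,
    ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y0, yend = .data$y1),
    linewidth = 0.3
  )
  if (!is.null(hits)) {
    h <- tidy(hits)
    if (nrow(h)) {
      p <- p + ggplot2::geom_point(data = h, ggplot2::aes(x = .data$x, y = .data$y),
                                   colour = "orange", size = 1.5)
      cur <- h[hits$cursor, ]
      p <- p + ggplot2::geom_point(data = cur, ggplot2::aes(x = .data$x, y = .data$y),
                                   colour = "red", shape = 1, size = 4, stroke = 1)
    }
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "branch-length units", y = "leaf index") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
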