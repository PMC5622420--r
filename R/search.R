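#' Parse an accession query with optional start/stop positions
#'
#' A sequence is addressed as `<accession>.<start>.<stop>`. If the final
#' two dot-separated fields of the query are both all-digits they are
#' taken as start/stop and the remainder (dots preserved) is the
#' accession prefix; otherwise the whole query is the prefix. This keeps
#' versioned accessions such as `"NR_074334.12"` intact: a single
#' trailing numeric field is part of the prefix, never a position.
#'
#' @param q Query string (non-empty; the empty string is a valid
#'   universal prefix for [search_sequences_by_accession()]).
#' @return A list with `prefix` (string), `start`, `stop` (integers or
#'   `NA`). `start > stop` raises a `phylomap_query_error`.
#' @examples
#' parse_accession_query("AB123456.1.1474")
#' parse_accession_query("NR_074334.12")
#' @export
parse_accession_query <- function(q) {
  stopifnot(is.character(q), length(q) == 1L)
  fields <- strsplit(q, ".", fixed = TRUE)[[1]]
  if (length(fields) >= 3L &&
      grepl("^[0-9]+$", fields[length(fields)]) &&
      grepl("^[0-9]+$", fields[length(fields) - 1L])) {
    start <- as.integer(fields[length(fields) - 1L])
    stop_ <- as.integer(fields[length(fields)])
    if (start > stop_) {
      abort_query(sprintf("start %d exceeds stop %d in accession query", start, stop_))
    }
    list(prefix = paste(fields[seq_len(length(fields) - 2L)], collapse = "."),
         start = start, stop = stop_)
  } else {
    list(prefix = q, start = NA_integer_, stop = NA_integer_)
  }
}

new_search_result_ <- function(kind, hits, cursor = if (nrow(hits)) 1L else 0L) {
  hits <- arrange(hits, .data$y, .data$id)
  structure(list(kind = kind, hits = hits, cursor = cursor),
            class = "phylomap_result")
}

#' @export
print.phylomap_result <- function(x, ...) {
  cat(sprintf("<phylomap_result> %s search, %d hit(s), cursor at %d\n",
              x$kind, nrow(x$hits), x$cursor))
  if (nrow(x$hits)) print(head(x$hits, 5))
  invisible(x)
}

seq_hits_ <- function(tree, layout, which_rows) {
  leaves <- layout$nodes[layout$nodes$is_leaf, ]
  s <- tree$sequences[which_rows, ]
  l <- leaves[which_rows, ]
  tibble(
    id = s$leaf_id,
    name = s$full_name,
    accession = s$accession,
    start = s$start, stop = s$stop,
    x = l$x, y = l$y
  )
}

#' Search sequences by accession prefix
#'
#' Returns every leaf whose accession starts (case-insensitively) with
#' the parsed prefix; when the query carries start/stop positions both
#' must also match exactly. The empty query is the universal prefix and
#' matches every sequence. Hits are ordered by layout y position
#' (ties by leaf ID) with the cursor on the first.
#'
#' @inheritParams compute_taxon_rects
#' @param q Query string, e.g. `"AB12"` or `"AB123456.1.1474"`.
#' @return A `phylomap_result` with `kind = "sequence"`.
#' @export
search_sequences_by_accession <- function(tree, layout, q) {
  pq <- parse_accession_query(q)
  acc <- tree$sequences$accession
  # base startsWith: the empty prefix is universal and matches everything
  hit <- startsWith(toupper(acc), toupper(pq$prefix))
  if (!is.na(pq$start)) {
    hit <- hit & tree$sequences$start == pq$start & tree$sequences$stop == pq$stop
  }
  new_search_result_("sequence", seq_hits_(tree, layout, which(hit)))
}

#' Search sequences by species name substring
#'
#' Case-insensitive substring match on the sequence `full_name`. An empty
#' query is rejected (`phylomap_query_error`): unlike the accession
#' prefix search there is no universal-substring reading that is not a
#' degenerate whole-tree result set.
#'
#' @inheritParams search_sequences_by_accession
#' @return A `phylomap_result` with `kind = "sequence"`.
#' @export
search_sequences_by_fullname <- function(tree, layout, q) {
  if (!nzchar(q)) abort_query("empty full-name query")
  hit <- str_detect(tree$sequences$full_name, fixed(q, ignore_case = TRUE))
  new_search_result_("sequence", seq_hits_(tree, layout, which(hit)))
}

taxon_hits_ <- function(rects, rows) {
  r <- rects[rows, ]
  tibble(
    id = as.character(r$taxon_id),
    name = r$taxon_name,
    rank = r$rank,
    x = r$x_lo, y = r$y_lo,
    x_lo = r$x_lo, x_hi = r$x_hi, y_lo = r$y_lo, y_hi = r$y_hi,
    sequence_count = r$sequence_count
  )
}

#' Search taxa by name substring
#'
#' Case-insensitive substring match on taxon names, at every rank. Hits
#' carry the taxon's rectangle so the result can be marked as a
#' rectangular feature.
#'
#' @inheritParams search_sequences_by_accession
#' @param rects Taxon rectangles from [compute_taxon_rects()].
#' @return A `phylomap_result` with `kind = "taxon"`.
#' @export
search_taxa_by_name <- function(tree, layout, q,
                                rects = compute_taxon_rects(tree, layout)) {
  if (!nzchar(q)) abort_query("empty taxon-name query")
  hit <- str_detect(rects$taxon_name, fixed(q, ignore_case = TRUE))
  new_search_result_("taxon", taxon_hits_(rects, which(hit)))
}

#' Search taxa by taxonomic-path substring, keeping only the most generic hits
#'
#' A taxon is a candidate when the query appears (case-insensitively) in
#' its full semicolon-joined path. Because every taxon nested inside a
#' matching group matches too, only the highest-rank results are
#' returned: a candidate is dropped exactly when one of its proper
#' ancestors is also a candidate, so every candidate is a
#' descendant-or-self of some returned taxon.
#'
#' @inheritParams search_taxa_by_name
#' @return A `phylomap_result` with `kind = "taxon"`.
#' @export
search_taxa_by_path <- function(tree, layout, q,
                                rects = compute_taxon_rects(tree, layout)) {
  if (!nzchar(q)) abort_query("empty taxon-path query")
  cand <- which(str_detect(rects$path, fixed(q, ignore_case = TRUE)))
  cand_ids <- rects$taxon_id[cand]
  parent_of <- setNames(rects$parent_taxon, as.character(rects$taxon_id))
  has_cand_ancestor <- map_lgl(cand_ids, function(id) {
    p <- parent_of[[as.character(id)]]
    while (!is.na(p)) {
      if (p %in% cand_ids) return(TRUE)
      p <- parent_of[[as.character(p)]]
    }
    FALSE
  })
  new_search_result_("taxon", taxon_hits_(rects, cand[!has_cand_ancestor]))
}

#' List taxa directly below the domains, for browsing
#'
#' One entry per annotated taxon whose nearest annotated ancestor is a
#' domain (phyla for *Bacteria*/*Archaea*-style domains, kingdoms or
#' major clades otherwise). Each entry carries a ready-made
#' `phylomap_result` holding the group itself (first, with the cursor on
#' it, so selecting the entry zooms there) followed by its direct
#' annotated children.
#'
#' @inheritParams search_taxa_by_name
#' @return A tibble, one row per entry, ordered by `y_lo`: `taxon_id`,
#'   `taxon_name`, `rank`, `sequence_count`, and a `result` list-column
#'   of `phylomap_result` objects.
#' @export
browse_phyla <- function(tree, layout,
                         rects = compute_taxon_rects(tree, layout)) {
  top_rank <- tree$rank_order[1]
  domains <- rects$taxon_id[rects$rank == top_rank]
  entries <- rects[rects$parent_taxon %in% domains & rects$rank != top_rank, ]
  entries <- arrange(entries, .data$y_lo)
  results <- map(entries$taxon_id, function(id) {
    self <- which(rects$taxon_id == id)
    kids <- which(rects$parent_taxon == id)
    hits <- taxon_hits_(rects, c(self, kids))
    # the group itself first, then its children by y; cursor on the group
    hits <- bind_rows(hits[1, ], arrange(hits[-1, ], .data$y, .data$id))
    structure(list(kind = "taxon", hits = hits, cursor = 1L),
              class = "phylomap_result")
  })
  tibble(
    taxon_id = entries$taxon_id,
    taxon_name = entries$taxon_name,
    rank = entries$rank,
    sequence_count = entries$sequence_count,
    result = results
  )
}

#' Navigate a search result set
#'
#' The results-navigator model: `next`/`previous` move the cursor
#' cyclically through the hits; `show_all` keeps the cursor and returns
#' a viewport bounding every hit; `exit` clears the result set. Every
#' direction also returns the viewport the viewer should move to:
#' for `next`/`previous` the current hit is centred at a zoom where it
#' has a comfortable on-screen size (a leaf pitch, or taxon rectangle
#' height, of at least `min_hit_px`), clamped to the padded world.
#'
#' @param results A `phylomap_result`.
#' @param direction One of `"next"`, `"previous"`, `"show_all"`,
#'   `"exit"`.
#' @param extent Occupied extent of the layout the results refer to.
#' @param view_px Assumed viewer size in pixels (square).
#' @param min_hit_px Minimum on-screen size of the focused hit.
#' @param tile_size,pad_frac,z_cap Tiling parameters (see
#'   [world_transform()]).
#' @return A list with `results` (updated `phylomap_result`) and
#'   `viewport` (a [viewport()], or `NULL` after `exit`).
#' @export
navigate <- function(results, direction = c("next", "previous", "show_all", "exit"),
                     extent, view_px = 768, min_hit_px = 32,
                     tile_size = 256L, pad_frac = 0.02, z_cap = 18L) {
  stopifnot(inherits(results, "phylomap_result"))
  direction <- match.arg(direction)
  n <- nrow(results$hits)
  if (direction %in% c("next", "previous") && n == 0L) {
    abort_state("cannot navigate an empty result set")
  }
  if (direction == "exit") {
    empty <- results$hits[0, ]
    return(list(results = new_search_result_(results$kind, empty),
                viewport = NULL))
  }
  if (direction == "show_all") {
    h <- results$hits
    box <- if (results$kind == "taxon") {
      c(x_lo = min(h$x_lo), x_hi = max(h$x_hi),
        y_lo = min(h$y_lo), y_hi = max(h$y_hi))
    } else {
      c(x_lo = min(h$x), x_hi = max(h$x), y_lo = min(h$y), y_hi = max(h$y))
    }
    vp <- fit_viewport_(box, extent, view_px, tile_size, pad_frac, z_cap)
    return(list(results = results, viewport = vp))
  }
  step <- if (direction == "next") 1L else -1L
  results$cursor <- ((results$cursor - 1L + step) %% n) + 1L
  hit <- results$hits[results$cursor, ]
  if (results$kind == "taxon") {
    cx <- (hit$x_lo + hit$x_hi) / 2
    cy <- (hit$y_lo + hit$y_hi) / 2
    size <- max(hit$y_hi - hit$y_lo, hit$x_hi - hit$x_lo)
  } else {
    cx <- hit$x
    cy <- hit$y
    size <- 1   # one leaf pitch
  }
  z <- 0L
  repeat {
    tr <- world_transform(extent, z, tile_size, pad_frac)
    if (tr$scale_y * size >= min_hit_px || z >= z_cap) break
    z <- z + 1L
  }
  tr <- world_transform(extent, z, tile_size, pad_frac)
  half <- view_px / tr$scale_y / 2
  win <- clamp_window_(c(x_lo = cx - half, x_hi = cx + half,
                         y_lo = cy - half, y_hi = cy + half),
                       tr$padded_extent)
  list(results = results,
       viewport = viewport(win[["x_lo"]], win[["x_hi"]], win[["y_lo"]],
                           win[["y_hi"]], z))
}

# Largest zoom at which `box` fits in view_px, window centred on it.
fit_viewport_ <- function(box, extent, view_px, tile_size, pad_frac, z_cap) {
  size <- max(box[["x_hi"]] - box[["x_lo"]], box[["y_hi"]] - box[["y_lo"]], 1e-9)
  z <- 0L
  while (z < z_cap) {
    tr <- world_transform(extent, z + 1L, tile_size, pad_frac)
    if (tr$scale_y * size > view_px) break
    z <- z + 1L
  }
  tr <- world_transform(extent, z, tile_size, pad_frac)
  half <- max(view_px / tr$scale_y, size * 1.0001) / 2
  cx <- (box[["x_lo"]] + box[["x_hi"]]) / 2
  cy <- (box[["y_lo"]] + box[["y_hi"]]) / 2
  win <- clamp_window_(c(x_lo = cx - half, x_hi = cx + half,
                         y_lo = cy - half, y_hi = cy + half),
                       tr$padded_extent)
  viewport(win[["x_lo"]], win[["x_hi"]], win[["y_lo"]], win[["y_hi"]], z)
}

# Shift (never shrink below its size) a window into the padded extent.
clamp_window_ <- function(win, padded) {
  wdx <- win[["x_hi"]] - win[["x_lo"]]
  wdy <- win[["y_hi"]] - win[["y_lo"]]
  wdx <- min(wdx, padded[["x_max"]] - padded[["x_min"]])
  wdy <- min(wdy, padded[["y_max"]] - padded[["y_min"]])
  x0 <- min(max(win[["x_lo"]], padded[["x_min"]]), padded[["x_max"]] - wdx)
  y0 <- min(max(win[["y_lo"]], padded[["y_min"]]), padded[["y_max"]] - wdy)
  c(x_lo = x0, x_hi = x0 + wdx, y_lo = y0, y_hi = y0 + wdy)
}
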