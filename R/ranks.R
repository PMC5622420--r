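#' Taxonomic rank order and the rank colour palette
#'
#' The rank vocabulary is configuration, not a constant: SILVA-style trees
#' use phylum below domain for *Bacteria*/*Archaea* but kingdom or major
#' clades for *Eukaryota*, so every function that interprets ranks takes an
#' ordered character vector, highest (most generic) rank first.
#'
#' `default_rank_order()` returns the six-rank vocabulary used throughout
#' the examples; `default_palette()` maps each rank to a `#RRGGBB` colour
#' (colours chosen for mutual distinctness; override any subset by passing
#' a named vector to the functions that take a `palette`).
#'
#' @param rank_order Ordered character vector of ranks, most generic first.
#' @return `default_rank_order()`: a character vector. `default_palette()`:
#'   a named character vector of `#RRGGBB` strings keyed by rank.
#' @examples
#' default_rank_order()
#' default_palette()[["phylum"]]
#' @export
default_rank_order <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' @rdname default_rank_order
#' @export
default_palette <- function(rank_order = default_rank_order()) {
  base <- c(
    domain = "#4D4D4D", phylum = "#E41A1C", class = "#377EB8",
    order = "#4DAF4A", family = "#984EA3", genus = "#FF7F00",
    kingdom = "#A65628", species = "#F781BF"
  )
  extra <- setdiff(rank_order, names(base))
  if (length(extra)) {
    # deterministic fallback hues for user-supplied ranks
    hues <- grDevices::hcl(h = seq(15, 375, length.out = length(extra) + 1L)[-1L],
                           c = 80, l = 55)
    base <- c(base, setNames(substr(hues, 1, 7), extra))
  }
  base[rank_order]
}

check_palette_ <- function(palette, ranks_needed) {
  missing <- setdiff(ranks_needed, names(palette))
  if (length(missing)) {
    abort_config(paste0(
      "palette has no colour for rank(s): ", paste(missing, collapse = ", ")
    ))
  }
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", palette[ranks_needed])
  if (any(bad)) {
    abort_config(paste0(
      "palette entries must be #RRGGBB; offending rank(s): ",
      paste(ranks_needed[bad], collapse = ", ")
    ))
  }
  invisible(palette)
}

rank_index_ <- function(rank, rank_order) {
  idx <- match(rank, rank_order)
  if (anyNA(idx)) {
    abort_config(paste0(
      "rank(s) not in the configured rank order: ",
      paste(unique(rank[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}
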