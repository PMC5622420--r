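#' Generate a synthetic SILVA-like annotated tree
#'
#' Deterministic (per seed) generator of tree + metadata fixtures at any
#' size, emulating the shape of an rRNA guide tree: a rooted, essentially
#' binary topology grown by random sequential leaf attachment (each new
#' leaf splits a uniformly chosen existing branch), exponential branch
#' lengths, a top-down taxonomic annotation of internal nodes in which
#' each rank level partitions the leaves into one or more named groups,
#' and per-leaf sequence records with accession (2 letters + 6 digits,
#' unique), alignment coordinates `start = 1`, `stop` uniform in
#' [900, 1600] (full-length rRNA gene scale), and a binomial-style
#' `full_name` derived from the most specific annotation above the leaf.
#'
#' Domains: when every child of the root subtends a clade, each root child
#' becomes one domain; otherwise the root itself is the single domain, so
#' every leaf path starts at the most generic rank either way. Below the
#' domains, each internal child of an annotated node is annotated at the
#' next rank with probability 0.9, or passed through unchanged (its own
#' children then get the chance), producing taxonomic paths of varying
#' depth as in real guide trees. For `n_leaves = 1` the tree is a chain of
#' one node per rank above the single leaf, so its path has full depth.
#'
#' @param n_leaves Number of leaves (>= 1).
#' @param seed Integer seed; the same seed always yields the identical
#'   tree (caller RNG state is untouched).
#' @param rank_order Ordered rank vocabulary, most generic first.
#' @param mean_branch_length Mean of the exponential branch-length draw, in
#'   branch-length (substitutions/site) units. The default, 0.05, keeps the
#'   root-to-leaf depth of large trees in the 0.5-2 range typical of rRNA
#'   guide trees.
#' @return A `phylomap_tree` (see [read_tree_map()]).
#' @examples
#' tr <- generate_fixture(50, seed = 1)
#' tr
#' @export
generate_fixture <- function(n_leaves, seed = 1L,
                             rank_order = default_rank_order(),
                             mean_branch_length = 0.05) {
  if (!is_count_(n_leaves) || n_leaves < 1) {
    abort("n_leaves must be a positive integer", class = "phylomap_argument_error")
  }
  if (!is.numeric(mean_branch_length) || mean_branch_length <= 0) {
    abort("mean_branch_length must be positive", class = "phylomap_argument_error")
  }
  n_leaves <- as.integer(n_leaves)
  with_seed_(seed, {
    if (n_leaves == 1L) {
      fixture_single_leaf_(rank_order, mean_branch_length)
    } else {
      fixture_multi_(n_leaves, rank_order, mean_branch_length)
    }
  })
}

# One leaf under a chain of one internal node per rank (root = domain).
fixture_single_leaf_ <- function(rank_order, mbl) {
  k <- length(rank_order)
  lens <- rexp(k, rate = 1 / mbl)
  nwk <- "L000001"
  for (i in seq_len(k)) {
    ri <- k - i + 1L   # innermost paren = lowest rank
    lab <- paste0(taxon_name_(rank_order[ri], 1L), "|", rank_order[ri])
    nwk <- paste0("(", nwk, ":", format(lens[i], digits = 12), ")",
                  if (ri > 1L) lab else "")
  }
  # outermost group label becomes the root's annotation (the domain)
  lab1 <- paste0(taxon_name_(rank_order[1], 1L), "|", rank_order[1])
  nwk <- paste0(nwk, lab1, ";")
  phy <- ape::read.tree(text = nwk)
  phy$node.label <- newick_internal_labels_(nwk)  # unary-chain label order
  meta <- leaf_metadata_(phy, rank_order)
  new_phylomap_tree(phy, meta, rank_order)
}

fixture_multi_ <- function(n, rank_order, mbl) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  child1 <- integer(n_nodes)
  child2 <- integer(n_nodes)
  blen <- numeric(n_nodes)
  is_leaf <- logical(n_nodes)

  # node 1 = root; 2,3 = first two leaves
  parent[1] <- 0L
  child1[1] <- 2L; child2[1] <- 3L
  parent[2] <- 1L; parent[3] <- 1L
  is_leaf[2] <- TRUE; is_leaf[3] <- TRUE
  blen[2] <- rexp(1, 1 / mbl); blen[3] <- rexp(1, 1 / mbl)
  n_cur <- 3L

  for (i in seq_len(n - 2L)) {
    v <- sample.int(n_cur - 1L, 1L) + 1L      # any non-root node
    u <- n_cur + 1L                            # new internal, splits edge to v
    l <- n_cur + 2L                            # new leaf
    p <- parent[v]
    if (child1[p] == v) child1[p] <- u else child2[p] <- u
    s <- runif(1)
    blen[u] <- blen[v] * s
    blen[v] <- blen[v] * (1 - s)
    parent[u] <- p
    child1[u] <- v
    child2[u] <- l
    parent[v] <- u
    parent[l] <- u
    is_leaf[l] <- TRUE
    blen[l] <- rexp(1, 1 / mbl)
    n_cur <- n_cur + 2L
  }

  anno <- annotate_fixture_(parent, child1, child2, is_leaf, rank_order)
  phy <- fixture_phylo_(parent, child1, child2, blen, is_leaf, anno)
  meta <- leaf_metadata_(phy, rank_order)
  new_phylomap_tree(phy, meta, rank_order)
}

taxon_name_ <- function(rank, counter) {
  sprintf("%s%s%03d", toupper(substr(rank, 1, 1)), substr(rank, 2, nchar(rank)),
          counter)
}

# Top-down rank assignment; returns character labels per node ("" if none).
annotate_fixture_ <- function(parent, child1, child2, is_leaf, rank_order) {
  n_nodes <- length(parent)
  k <- length(rank_order)
  label <- character(n_nodes)
  counters <- integer(k)
  annotate <- function(node, ri) {
    counters[ri] <<- counters[ri] + 1L
    label[node] <<- paste0(taxon_name_(rank_order[ri], counters[ri]), "|",
                           rank_order[ri])
  }
  # preallocated BFS queue (every internal node is visited exactly once)
  queue_node <- integer(n_nodes)
  queue_rank <- integer(n_nodes)
  qn <- 0L
  push <- function(node, r) {
    qn <<- qn + 1L
    queue_node[qn] <<- node
    queue_rank[qn] <<- r
  }
  root_kids <- c(child1[1], child2[1])
  root_kids <- root_kids[root_kids != 0L]
  if (all(!is_leaf[root_kids])) {
    for (ch in root_kids) {
      annotate(ch, 1L)
      push(ch, 1L)
    }
  } else {
    annotate(1L, 1L)
    push(1L, 1L)
  }
  qi <- 1L
  while (qi <= qn) {
    v <- queue_node[qi]; r <- queue_rank[qi]; qi <- qi + 1L
    for (ch in c(child1[v], child2[v])) {
      if (ch == 0L || is_leaf[ch]) next
      if (r < k && runif(1) < 0.9) {
        annotate(ch, r + 1L)
        push(ch, r + 1L)
      } else {
        push(ch, r)
      }
    }
  }
  label
}

# Assemble an ape phylo (tips numbered in preorder appearance = file order).
fixture_phylo_ <- function(parent, child1, child2, blen, is_leaf, anno) {
  n_nodes <- length(parent)
  n_tip <- sum(is_leaf)
  # preorder traversal preserving child order
  ord <- integer(n_nodes)
  stack <- 1L
  j <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    j <- j + 1L
    ord[j] <- v
    kids <- c(child1[v], child2[v])
    kids <- kids[kids != 0L]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  newid <- integer(n_nodes)
  tip_ct <- 0L
  int_ct <- 0L
  for (v in ord) {
    if (is_leaf[v]) {
      tip_ct <- tip_ct + 1L
      newid[v] <- tip_ct
    } else {
      int_ct <- int_ct + 1L
      newid[v] <- n_tip + int_ct
    }
  }
  has_par <- parent != 0L
  kid_old <- which(has_par)
  # edges in cladewise order: sort by parent's preorder position, then slot
  pre_pos <- integer(n_nodes); pre_pos[ord] <- seq_len(n_nodes)
  eo <- order(pre_pos[kid_old])
  kid_old <- kid_old[eo]
  edge <- cbind(newid[parent[kid_old]], newid[kid_old])
  phy <- structure(list(
    edge = edge,
    edge.length = blen[kid_old],
    Nnode = n_nodes - n_tip,
    tip.label = sprintf("L%06d", seq_len(n_tip)),
    node.label = {
      il <- ord[!is_leaf[ord]]
      anno[il]
    }
  ), class = "phylo", order = "cladewise")
  phy
}

# Metadata rows for each tip, derived from the annotations on its path.
leaf_metadata_ <- function(phy, rank_order) {
  n_tip <- length(phy$tip.label)
  n_nodes <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  tok <- rep(NA_character_, n_nodes)
  nl <- phy$node.label %||% character(phy$Nnode)
  has <- !is.na(nl) & nl != ""
  tok[(n_tip + 1L):n_nodes][has] <- nl[has]
  # path strings top-down (parents precede children in cladewise edges)
  path <- rep("", n_nodes)
  root <- n_tip + 1L
  path[root] <- if (!is.na(tok[root])) tok[root] else ""
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    path[v] <- if (!is.na(tok[v])) {
      if (path[p] == "") tok[v] else paste0(path[p], ";", tok[v])
    } else path[p]
  }
  leaf_paths <- path[seq_len(n_tip)]
  deepest <- vapply(strsplit(leaf_paths, ";", fixed = TRUE), function(tk) {
    last <- tk[length(tk)]
    strsplit(last, "|", fixed = TRUE)[[1]][1]
  }, character(1))
  digits <- sample.int(999999L, n_tip)
  prefix <- paste0(sample(LETTERS, n_tip, replace = TRUE),
                   sample(LETTERS, n_tip, replace = TRUE))
  tibble(
    leaf_id = phy$tip.label,
    accession = sprintf("%s%06d", prefix, digits),
    start = 1L,
    stop = sample(900:1600, n_tip, replace = TRUE),
    full_name = sprintf("%s species%04d", deepest, seq_len(n_tip)),
    taxonomic_path = leaf_paths
  )
}
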