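test_that("accession queries parse the trailing position fields", {
  q <- parse_accession_query("AB123456.1.1474")
  expect_equal(q, list(prefix = "AB123456", start = 1L, stop = 1474L))
  expect_equal(parse_accession_query("AB12"),
               list(prefix = "AB12", start = NA_integer_, stop = NA_integer_))
  # one trailing numeric field is a version suffix, not a position
  expect_equal(parse_accession_query("NR_074334.12")$prefix, "NR_074334.12")
  # dots inside the prefix survive
  expect_equal(parse_accession_query("NR_074334.2.50.900")$prefix, "NR_074334.2")
  expect_error(parse_accession_query("AB123456.90.10"),
               class = "phylomap_query_error")
})

test_that("accession search matches prefixes case-insensitively", {
  st <- cached_stack(1000, seed = 12)
  tree <- st$tree
  acc <- tree$sequences$accession[123]
  r <- search_sequences_by_accession(tree, st$layout, acc)
  expect_equal(nrow(r$hits), 1L)
  expect_equal(r$hits$accession, acc)
  expect_equal(r$cursor, 1L)
  # lower-case query matches too
  r2 <- search_sequences_by_accession(tree, st$layout, tolower(acc))
  expect_equal(r2$hits$accession, acc)
  # full <accession>.<start>.<stop> address
  full <- sprintf("%s.%d.%d", acc, 1, tree$sequences$stop[123])
  expect_equal(nrow(search_sequences_by_accession(tree, st$layout, full)$hits), 1L)
  wrong <- sprintf("%s.%d.%d", acc, 2, tree$sequences$stop[123])
  expect_equal(nrow(search_sequences_by_accession(tree, st$layout, wrong)$hits), 0L)
  # empty query is the universal prefix
  expect_equal(nrow(search_sequences_by_accession(tree, st$layout, "")$hits),
               tree$n_leaves)
})

test_that("search results agree with linear-scan predicate oracles", {
  withr::local_seed(31)
  st <- cached_stack(1000, seed = 12)
  tree <- st$tree; lay <- st$layout; rects <- st$rects
  seqs <- tree$sequences
  for (k in 1:50) {
    # accession prefix oracle
    pref <- substr(seqs$accession[sample.int(nrow(seqs), 1)], 1, sample(1:8, 1))
    got <- search_sequences_by_accession(tree, lay, pref)
    expect_same_hits(got, seqs$leaf_id[startsWith(seqs$accession, pref)])
    # full-name substring oracle (random 3-gram)
    nm <- seqs$full_name[sample.int(nrow(seqs), 1)]
    i <- sample.int(nchar(nm) - 2, 1)
    ngram <- substr(nm, i, i + 2)
    got <- search_sequences_by_fullname(tree, lay, ngram)
    expect_same_hits(got, seqs$leaf_id[grepl(ngram, seqs$full_name,
                                             ignore.case = TRUE, fixed = FALSE)])
  }
  for (k in 1:20) {
    tn <- rects$taxon_name[sample.int(nrow(rects), 1)]
    sub <- substr(tn, 1, sample(3:nchar(tn), 1))
    got <- search_taxa_by_name(tree, lay, sub, rects)
    expect_same_hits(got, rects$taxon_id[grepl(sub, rects$taxon_name,
                                               ignore.case = TRUE)])
  }
})

test_that("hits come ordered by y position with ties broken by id", {
  st <- cached_stack(1000, seed = 12)
  r <- search_sequences_by_accession(st$tree, st$layout, "")
  expect_true(!is.unsorted(r$hits$y))
  r2 <- search_taxa_by_name(st$tree, st$layout, "0", st$rects)
  expect_true(!is.unsorted(r2$hits$y))
  ties <- split(r2$hits$id, r2$hits$y)
  for (g in ties) expect_true(!is.unsorted(g))
})

test_that("path search suppresses descendants of matching ancestors", {
  st <- cached_stack(1000, seed = 12)
  rects <- st$rects
  # querying a phylum name returns only that phylum, not nested groups
  phy <- rects$taxon_name[rects$rank == "phylum"][1]
  got <- search_taxa_by_path(st$tree, st$layout, phy, rects)
  cand <- rects$taxon_id[grepl(phy, rects$path, ignore.case = TRUE)]
  expect_gt(length(cand), nrow(got$hits) - 1)  # candidates include descendants
  # (a) no returned taxon has a candidate proper ancestor
  parent_of <- setNames(rects$parent_taxon, rects$taxon_id)
  for (id in got$hits$id) {
    p <- parent_of[[id]]
    while (!is.na(p)) {
      expect_false(p %in% cand)
      p <- parent_of[[as.character(p)]]
    }
  }
  # (b) every candidate is a descendant-or-self of some returned taxon
  for (id in cand) {
    v <- id; ok <- FALSE
    while (!is.na(v)) {
      if (as.character(v) %in% got$hits$id) { ok <- TRUE; break }
      v <- parent_of[[as.character(v)]]
    }
    expect_true(ok)
  }
  # a domain name returns exactly the domain taxa (no ancestors exist)
  dom <- st$tree$rank_order[1]
  domname <- rects$taxon_name[rects$rank == dom][1]
  gd <- search_taxa_by_path(st$tree, st$layout, domname, rects)
  expect_same_hits(gd, rects$taxon_id[rects$taxon_name == domname])
})

test_that("random path substrings obey the suppression oracle", {
  withr::local_seed(17)
  st <- cached_stack(1000, seed = 13)
  rects <- st$rects
  parent_of <- setNames(rects$parent_taxon, rects$taxon_id)
  for (k in 1:25) {
    p <- rects$path[sample.int(nrow(rects), 1)]
    i <- sample.int(max(nchar(p) - 4, 1), 1)
    q <- substr(p, i, i + 4)
    got <- search_taxa_by_path(st$tree, st$layout, q, rects)
    cand <- rects$taxon_id[grepl(tolower(q), tolower(rects$path), fixed = TRUE)]
    keep <- vapply(cand, function(id) {
      a <- parent_of[[as.character(id)]]
      while (!is.na(a)) {
        if (a %in% cand) return(FALSE)
        a <- parent_of[[as.character(a)]]
      }
      TRUE
    }, logical(1))
    expect_same_hits(got, cand[keep])
  }
})

test_that("empty substring queries are rejected, empty results are fine", {
  st <- cached_stack(100, seed = 5)
  expect_error(search_sequences_by_fullname(st$tree, st$layout, ""),
               class = "phylomap_query_error")
  expect_error(search_taxa_by_name(st$tree, st$layout, "", st$rects),
               class = "phylomap_query_error")
  r <- search_taxa_by_name(st$tree, st$layout, "zzz-no-such", st$rects)
  expect_equal(nrow(r$hits), 0L)
  expect_equal(r$cursor, 0L)
})

test_that("browse lists groups directly under the domains", {
  st <- cached_stack(1000, seed = 12)
  rects <- st$rects
  br <- browse_phyla(st$tree, st$layout, rects)
  doms <- rects$taxon_id[rects$rank == "domain"]
  want <- rects$taxon_id[rects$parent_taxon %in% doms]
  expect_setequal(br$taxon_id, want)
  # each entry's result set starts with the group itself, cursor on it
  for (i in seq_len(nrow(br))) {
    res <- br$result[[i]]
    expect_equal(res$hits$id[1], as.character(br$taxon_id[i]))
    expect_equal(res$cursor, 1L)
    kids <- rects$taxon_id[!is.na(rects$parent_taxon) &
                             rects$parent_taxon == br$taxon_id[i]]
    expect_setequal(res$hits$id[-1], as.character(kids))
  }
})

test_that("browse is empty when only domains are annotated", {
  nw <- withr::local_tempfile(); md <- withr::local_tempfile()
  writeLines("((A:1,B:2):1,C:3)Dom1|domain;", nw)
  writeLines(c(
    "leaf_id\taccession\tstart\tstop\tfull_name\ttaxonomic_path",
    "A\tAA000001\t1\t1000\tGx alpha\tDom1|domain",
    "B\tAA000002\t1\t1000\tGx beta\tDom1|domain",
    "C\tAA000003\t1\t1000\tGx gamma\tDom1|domain"
  ), md)
  tree <- read_tree_map(nw, md)
  lay <- compute_layout(tree)
  expect_equal(nrow(browse_phyla(tree, lay)), 0L)
})

test_that("navigator cycles, centres hits, bounds all, and exits", {
  st <- cached_stack(1000, seed = 12)
  ext <- st$layout$extent
  res <- search_sequences_by_fullname(st$tree, st$layout, "species")
  n <- nrow(res$hits)
  expect_gt(n, 3)
  # cyclic next from the last hit wraps to the first
  res$cursor <- n
  nav <- navigate(res, "next", ext)
  expect_equal(nav$results$cursor, 1L)
  nav <- navigate(nav$results, "previous", ext)
  expect_equal(nav$results$cursor, n)
  # centre property: the hit sits in the middle 50% of the viewport
  # (unless clamped at the world border)
  withr::local_seed(23)
  for (k in 1:20) {
    res$cursor <- sample.int(n, 1)
    nav <- navigate(res, "next", ext)
    hit <- nav$results$hits[nav$results$cursor, ]
    w <- nav$viewport$window
    dy <- w[["y_hi"]] - w[["y_lo"]]
    at_border <- w[["y_lo"]] <= 1e-9 ||
      w[["y_hi"]] >= world_transform(ext, nav$viewport$zoom)$padded_side - 1e-9
    if (!at_border) {
      expect_gte(hit$y, w[["y_lo"]] + dy / 4)
      expect_lte(hit$y, w[["y_hi"]] - dy / 4)
    }
    # the focused hit is at least min_hit_px on screen (or zoom is capped)
    tr <- world_transform(ext, nav$viewport$zoom)
    expect_true(tr$scale_y >= 32 || nav$viewport$zoom == 18L)
  }
  # show_all bounds every hit
  nav <- navigate(res, "show_all", ext)
  w <- nav$viewport$window
  expect_true(all(res$hits$y >= w[["y_lo"]] - 1e-9 & res$hits$y <= w[["y_hi"]] + 1e-9))
  # exit clears the set
  nav <- navigate(res, "exit", ext)
  expect_equal(nrow(nav$results$hits), 0L)
  expect_null(nav$viewport)
  # navigating an empty set is a state error
  expect_error(navigate(nav$results, "next", ext), class = "phylomap_state_error")
})
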