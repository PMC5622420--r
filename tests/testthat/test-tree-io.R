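test_that("Newick + metadata parsing preserves leaf order and structure", {
  nw <- withr::local_tempfile(fileext = ".nwk")
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines("((A:1,B:2)Phy1|phylum:1,C:3)Dom1|domain;", nw)
  writeLines(c(
    "leaf_id\taccession\tstart\tstop\tfull_name\ttaxonomic_path",
    "C\tAA000003\t1\t1000\tGx gamma\tDom1|domain",
    "A\tAA000001\t1\t1000\tGx alpha\tDom1|domain;Phy1|phylum",
    "B\tAA000002\t1\t1000\tGx beta\tDom1|domain;Phy1|phylum"
  ), md)
  tree <- read_tree_map(nw, md)
  expect_equal(tree$n_leaves, 3L)
  expect_equal(tree$phylo$Nnode, 2L)
  # leaf order as written in the Newick string, not metadata row order
  expect_equal(tree$phylo$tip.label, c("A", "B", "C"))
  expect_equal(tree$sequences$leaf_id, c("A", "B", "C"))
  expect_equal(nrow(tree$sequences), tree$n_leaves)
  expect_setequal(tree$taxa$taxon_name, c("Dom1", "Phy1"))
})

test_that("single-leaf Newick parses to a root with one child", {
  nw <- withr::local_tempfile()
  md <- withr::local_tempfile()
  writeLines("(A:1)Dom1|domain;", nw)
  writeLines(c(
    "leaf_id\taccession\tstart\tstop\tfull_name\ttaxonomic_path",
    "A\tAA000001\t1\t1000\tGx alpha\tDom1|domain"
  ), md)
  tree <- read_tree_map(nw, md)
  expect_equal(tree$n_leaves, 1L)
  expect_equal(sum(tree$nodes$parent == 2L, na.rm = TRUE), 1L)
})

test_that("malformed input raises classed errors with diagnostics", {
  nw <- withr::local_tempfile()
  md <- withr::local_tempfile()
  writeLines(c(
    "leaf_id\taccession\tstart\tstop\tfull_name\ttaxonomic_path",
    "A\tAA000001\t1\t1000\tGx alpha\tDom1|domain"
  ), md)

  writeLines("((A:1,B:2):1;", nw)   # unbalanced '('
  err <- expect_error(read_tree_map(nw, md), class = "phylomap_parse_error")
  expect_true(is.numeric(err$offset) && err$offset > 0)

  writeLines("(A:1,B:2))X:1;", nw)  # unbalanced ')'
  err <- expect_error(read_tree_map(nw, md), class = "phylomap_parse_error")
  expect_true(is.numeric(err$offset))

  writeLines("(A:1)Dom1|domain", nw)  # missing ';'
  expect_error(read_tree_map(nw, md), class = "phylomap_parse_error")

  # leaf/metadata reconciliation, listing offenders both ways
  writeLines("((A:1,B:2)Phy1|phylum:1,C:3)Dom1|domain;", nw)
  err <- expect_error(read_tree_map(nw, md), class = "phylomap_reconcile_error")
  expect_setequal(err$leaves_without_metadata, c("B", "C"))

  # stored path disagreeing with tree annotations names the leaf
  writeLines("(A:1)Dom1|domain;", nw)
  md2 <- withr::local_tempfile()
  writeLines(c(
    "leaf_id\taccession\tstart\tstop\tfull_name\ttaxonomic_path",
    "A\tAA000001\t1\t1000\tGx alpha\tOther|domain"
  ), md2)
  err <- expect_error(read_tree_map(nw, md2), class = "phylomap_consistency_error")
  expect_match(conditionMessage(err), "A")
})

test_that("missing branch lengths are zero-filled with a warning", {
  nw <- withr::local_tempfile()
  md <- withr::local_tempfile()
  writeLines("((A:1,B)Phy1|phylum:1,C:3)Dom1|domain;", nw)
  writeLines(c(
    "leaf_id\taccession\tstart\tstop\tfull_name\ttaxonomic_path",
    "A\tAA000001\t1\t1000\tGx alpha\tDom1|domain;Phy1|phylum",
    "B\tAA000002\t1\t1000\tGx beta\tDom1|domain;Phy1|phylum",
    "C\tAA000003\t1\t1000\tGx gamma\tDom1|domain"
  ), md)
  expect_warning(tree <- read_tree_map(nw, md), "branch length")
  expect_equal(tree$nodes$branch_length[2], 0)
})

test_that("write -> read round-trips trees exactly", {
  for (n in c(3, 50, 1000)) {
    tree <- cached_fixture(n, seed = 1)
    nw <- withr::local_tempfile()
    md <- withr::local_tempfile()
    write_tree_map(tree, nw, md)
    back <- read_tree_map(nw, md)
    expect_identical(back$phylo$tip.label, tree$phylo$tip.label)
    expect_identical(back$phylo$edge, tree$phylo$edge)
    expect_lt(max(abs(back$phylo$edge.length - tree$phylo$edge.length)), 1e-9)
    expect_identical(as.data.frame(back$sequences), as.data.frame(tree$sequences))
    expect_identical(back$taxa$taxon_name, tree$taxa$taxon_name)
    expect_identical(back$taxa$rank, tree$taxa$rank)
  }
})

test_that("internal nodes without annotation serialize without labels", {
  tree <- cached_fixture(20, seed = 2)
  nw <- withr::local_tempfile()
  md <- withr::local_tempfile()
  write_tree_map(tree, nw, md)
  txt <- paste(readLines(nw), collapse = "")
  n_annotated <- nrow(tree$taxa)
  expect_equal(lengths(regmatches(txt, gregexpr("\\|", txt))), n_annotated)
})

test_that("fixture generation is deterministic and leaves RNG state alone", {
  a <- generate_fixture(25, seed = 7)
  set.seed(99)
  before <- runif(1)
  b <- generate_fixture(25, seed = 7)
  set.seed(99)
  expect_equal(runif(1), before)   # generator did not disturb caller RNG
  nw1 <- withr::local_tempfile(); md1 <- withr::local_tempfile()
  nw2 <- withr::local_tempfile(); md2 <- withr::local_tempfile()
  write_tree_map(a, nw1, md1)
  write_tree_map(b, nw2, md2)
  expect_identical(readLines(nw1), readLines(nw2))
  expect_identical(readLines(md1), readLines(md2))
})

test_that("single-leaf fixture carries a full-depth taxonomic path", {
  tree <- generate_fixture(1, seed = 4)
  path <- strsplit(tree$sequences$taxonomic_path, ";", fixed = TRUE)[[1]]
  expect_length(path, length(default_rank_order()))
  expect_match(path[1], "\\|domain$")
  expect_match(path[length(path)], "\\|genus$")
})

test_that("generated trees satisfy all container invariants", {
  for (seed in c(7, 8)) {
    tree <- cached_fixture(2000, seed)
    expect_silent(validate_tree(tree))
    # leaf paths equal the annotation chain on the root-to-leaf path
    expect_identical(phylomap:::leaf_annotation_paths_(tree),
                     tree$sequences$taxonomic_path)
    # accessions are 2 letters + 6 digits and unique
    expect_true(all(grepl("^[A-Z]{2}[0-9]{6}$", tree$sequences$accession)))
    expect_false(anyDuplicated(tree$sequences$accession) > 0)
    expect_true(all(tree$sequences$start == 1L))
    expect_true(all(tree$sequences$stop >= 900 & tree$sequences$stop <= 1600))
  }
  expect_error(generate_fixture(0), class = "phylomap_argument_error")
})
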