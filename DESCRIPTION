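Package: phylomap
Title: Zoomable Map Engine for Large Annotated Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns very large annotated phylogenetic trees into a zoomable,
    slippy-map style view: a rectangular phylogram layout in world
    coordinates, per-clade taxon rectangles coloured by rank, a spatial
    feature index, a raster tile pyramid with level-of-detail rules, and
    the navigation, taxonomic-context and search queries a tree browser
    needs (taxon bar, taxonomy brackets, minimap, scale bar, accession and
    taxon search with a results navigator). Includes a deterministic
    synthetic fixture generator producing SILVA-like tree and metadata
    pairs so the whole pipeline runs without external data, and a minimal
    append-only store for curator feedback reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
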