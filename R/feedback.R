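#' File a feedback report against tree elements
#'
#' The two-step data-problem workflow reduced to its data contract:
#' a selection of tree elements (leaf IDs and/or taxon references of the
#' form `"taxon#<id>"`) plus a categorised free-text report, appended as
#' one JSON object per line to an append-only store. `data_problem`
#' reports must select at least one element (they describe specific
#' data); the other categories may leave the selection empty. Every
#' referenced element must exist in the tree.
#'
#' @inheritParams compute_layout
#' @param selection Character vector of element references (may be
#'   empty for categories other than `data_problem`).
#' @param category One of `"data_problem"`, `"technical_problem"`,
#'   `"feature_request"`, `"question"`.
#' @param description Free-text report body.
#' @param store Path of the JSON-lines report store (created on first
#'   use).
#' @return The filed report as a list (with generated `report_id` and
#'   `created` timestamp), invisibly.
#' @export
file_report <- function(tree, selection, category, description, store) {
  stopifnot(inherits(tree, "phylomap_tree"))
  categories <- c("data_problem", "technical_problem", "feature_request",
                  "question")
  if (!is.character(category) || length(category) != 1L ||
      !category %in% categories) {
    abort_validation(paste0("category must be one of: ",
                            paste(categories, collapse = ", ")))
  }
  selection <- as.character(selection %||% character(0))
  if (category == "data_problem" && length(selection) == 0L) {
    abort_validation("a data_problem report requires a non-empty selection")
  }
  is_taxon <- str_starts(selection, stringr::fixed("taxon#"))
  taxon_ids <- suppressWarnings(as.integer(sub("^taxon#", "", selection[is_taxon])))
  bad_taxon <- is.na(taxon_ids) | !(taxon_ids %in% tree$taxa$taxon_id)
  bad_leaf <- !(selection[!is_taxon] %in% tree$sequences$leaf_id)
  if (any(bad_taxon) || any(bad_leaf)) {
    dangling <- c(selection[is_taxon][bad_taxon], selection[!is_taxon][bad_leaf])
    abort_reference(paste0("selection references unknown element(s): ",
                           paste(head(dangling, 10), collapse = ", ")))
  }
  n_prev <- if (file.exists(store)) length(readLines(store, warn = FALSE)) else 0L
  record <- list(
    report_id = sprintf("R%06d-%s", n_prev + 1L,
                        substr(md5_string_(paste(category, description,
                                                 paste(selection, collapse = ","),
                                                 n_prev)), 1, 8)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    category = category,
    selection = selection,
    description = description
  )
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  con <- tryCatch(file(store, open = "a", encoding = "UTF-8"),
                  error = function(e) abort_io(paste0("cannot open report store ", store)))
  on.exit(close(con), add = TRUE)
  writeLines(line, con)
  invisible(record)
}

#' Read all reports from a JSON-lines store
#'
#' @param store Path to the store written by [file_report()].
#' @return A tibble, one row per report in filing order: `report_id`,
#'   `created`, `category`, `description`, and a `selection`
#'   list-column. Zero rows if the store does not exist yet.
#' @export
read_reports <- function(store) {
  empty <- tibble(report_id = character(), created = character(),
                  category = character(), description = character(),
                  selection = list())
  if (!file.exists(store)) return(empty)
  lines <- readLines(store, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  recs <- map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  tibble(
    report_id = map_chr(recs, "report_id"),
    created = map_chr(recs, "created"),
    category = map_chr(recs, "category"),
    description = map_chr(recs, "description"),
    selection = map(recs, function(r) as.character(r$selection %||% character(0)))
  )
}
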