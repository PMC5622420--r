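#' Read a project configuration file
#'
#' INI-style `key = value` configuration with `[section]` headers, parsed
#' once and validated eagerly. Recognised sections and keys:
#'
#' \describe{
#'   \item{`[paths]`}{`tree`, `metadata` (inputs), `build_dir` (artifact
#'     directory), `reports` (feedback store). Relative paths are
#'     resolved against the config file's directory.}
#'   \item{`[tiles]`}{`tile_size` (default 256), `pad_frac` (default
#'     0.02), `z_max` (integer, or `auto`).}
#'   \item{`[lod]`}{`min_leaf_pitch_px`, `min_rect_height_px`,
#'     `min_bracket_height_px`, `label_font_px` (see [lod_policy()]).}
#'   \item{`[palette]`}{one `rank = #RRGGBB` entry per rank to override
#'     the default palette.}
#'   \item{`[ranks]`}{`order`: semicolon-separated rank names, most
#'     generic first.}
#' }
#'
#' @param path Path to the config file.
#' @param check_paths Validate that input paths exist (build time wants
#'   this; fixture generation does not).
#' @return A `phylomap_config` list: `paths`, `tile_size`, `pad_frac`,
#'   `z_max` (`NULL` = auto), `lod` ([lod_policy()]), `palette`,
#'   `rank_order`, and `config_string` (the canonical serialized form
#'   used for hashing).
#' @export
read_config <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) abort_io(paste0("no such config file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  # full-line comments only: '#' also appears inside #RRGGBB values
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      abort_parse(paste0("config line is neither [section] nor key = value: ", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[paste0(section, ".", key)]] <- val
  }
  get <- function(name, default = NULL) kv[[name]] %||% default
  num <- function(name, default) {
    v <- get(name)
    if (is.null(v)) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) abort_parse(paste0("config value for ", name, " is not numeric: ", v))
    x
  }
  base_dir <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  paths <- list(
    tree = resolve(get("paths.tree")),
    metadata = resolve(get("paths.metadata")),
    build_dir = resolve(get("paths.build_dir", "build")),
    reports = resolve(get("paths.reports", "reports.jsonl"))
  )
  rank_order <- {
    v <- get("ranks.order")
    if (is.null(v)) default_rank_order() else trimws(strsplit(v, ";", fixed = TRUE)[[1]])
  }
  palette <- default_palette(rank_order)
  pal_keys <- grep("^palette\\.", names(kv), value = TRUE)
  for (k in pal_keys) palette[sub("^palette\\.", "", k)] <- kv[[k]]
  check_palette_(palette, rank_order)
  z_max_raw <- get("tiles.z_max", "auto")
  z_max <- if (identical(z_max_raw, "auto")) NULL else {
    z <- suppressWarnings(as.integer(z_max_raw))
    if (is.na(z) || z < 0) abort_parse("tiles.z_max must be a non-negative integer or 'auto'")
    z
  }
  lod <- lod_policy(
    min_leaf_pitch_px = num("lod.min_leaf_pitch_px", 8),
    min_rect_height_px = num("lod.min_rect_height_px", 2),
    min_bracket_height_px = num("lod.min_bracket_height_px", 12),
    label_font_px = num("lod.label_font_px", 10)
  )
  if (check_paths) {
    for (nm in c("tree", "metadata")) {
      p <- paths[[nm]]
      if (is.null(p)) abort_config(paste0("config is missing paths.", nm))
      if (!file.exists(p)) abort_io(paste0("paths.", nm, " does not exist: ", p))
    }
  }
  cfg <- list(
    paths = paths,
    tile_size = as.integer(num("tiles.tile_size", 256)),
    pad_frac = num("tiles.pad_frac", 0.02),
    z_max = z_max,
    lod = lod,
    palette = palette,
    rank_order = rank_order
  )
  cfg$config_string <- jsonlite::toJSON(
    list(tile_size = cfg$tile_size, pad_frac = cfg$pad_frac,
         z_max = cfg$z_max %||% "auto", lod = unclass(lod),
         palette = as.list(palette), rank_order = rank_order),
    auto_unbox = TRUE, digits = NA
  )
  structure(cfg, class = "phylomap_config")
}
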