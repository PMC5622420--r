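# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

abort_parse <- function(msg, ...) abort(msg, class = "phylomap_parse_error", ...)
abort_reconcile <- function(msg, ...) abort(msg, class = "phylomap_reconcile_error", ...)
abort_consistency <- function(msg, ...) abort(msg, class = "phylomap_consistency_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "phylomap_config_error", ...)
abort_query <- function(msg, ...) abort(msg, class = "phylomap_query_error", ...)
abort_state <- function(msg, ...) abort(msg, class = "phylomap_state_error", ...)
abort_io <- function(msg, ...) abort(msg, class = "phylomap_io_error", ...)
abort_address <- function(msg, ...) abort(msg, class = "phylomap_address_error", ...)
abort_reference <- function(msg, ...) abort(msg, class = "phylomap_reference_error", ...)
abort_validation <- function(msg, ...) abort(msg, class = "phylomap_validation_error", ...)

# Closed-interval overlap test, vectorised.
intervals_overlap_ <- function(a_lo, a_hi, b_lo, b_hi) {
  a_lo <= b_hi & b_lo <= a_hi
}

# md5 of a character scalar, via a temporary file (no digest dependency).
md5_string_ <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

is_count_ <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == trunc(x)
}
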