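# Internal helpers shared across modules.

# Collapse a character/integer set into a canonical ";"-joined token string.
# Canonical = unique values, sorted, so two edges with the same set compare equal.
join_set <- function(x) {
  x <- unique(as.character(x))
  x <- x[!is.na(x) & nzchar(x)]
  paste(sort(x), collapse = ";")
}

split_set <- function(x) {
  strsplit(x, ";", fixed = TRUE)
}

split_int_set <- function(x) {
  lapply(split_set(x), as.integer)
}

# Vectorised "is class c in the canonical class string".
set_contains <- function(x, value) {
  vapply(split_set(x), function(s) as.character(value) %in% s, logical(1))
}

#' Normalize gene-symbol tokens
#'
#' Upper-cases and strips surrounding whitespace. Symbols are matched exactly
#' after this normalization; no alias resolution is attempted.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "rasnet_config_error")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "rasnet_format_error")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Round half away from zero (so 0.5 -> 1, 2.5 -> 3), used for weighted counts
# entering an exact test on integers.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
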