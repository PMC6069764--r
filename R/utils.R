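# Internal helpers shared across modules.

MULTI_SEP <- "|"

#' @noRd
split_multi <- function(x) {
  # "" -> character(0); "a|b" -> c("a","b")
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) character(0)
    else strsplit(cell, MULTI_SEP, fixed = TRUE)[[1L]]
  })
}

#' @noRd
join_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = MULTI_SEP), character(1))
}

#' Round half-up to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; reduction percentages are reported
#' with conventional half-up rounding (e.g. 91.75 -> 91.8).
#' @noRd
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Normalize user-facing label text: case-fold and collapse whitespace
#' @noRd
norm_label <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Deterministic slug identifier derived from a label
#'
#' Lowercase, punctuation stripped, whitespace runs joined with hyphens.
#' "Leukemia, B-Cell" -> "leukemia-b-cell".
#' @param label character vector of term labels.
#' @return character vector of slugs.
#' @export
#' @examples
#' term_slug("Neoplasms by Histologic Type")
term_slug <- function(label) {
  x <- tolower(trimws(label))
  x <- gsub("[^a-z0-9]+", "-", x)
  gsub("^-+|-+$", "", x)
}

# Classed conditions: usage/configuration errors vs data validation errors,
# mapped to distinct exit codes by the command-line layer.

#' @noRd
usage_error <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("meshmir_usage_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @noRd
data_error <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("meshmir_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator for reproducible synthetic output without disturbing
#' the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
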