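# Internal helpers shared across modules.

#' Behavior class alphabet
#'
#' The three behavior classes scored in the round-arena assay, in canonical
#' order. All label tracks, probability matrices and behavior fractions use
#' this ordering.
#'
#' @return Character vector `c("running", "sitting", "grooming")`.
#' @export
behavior_classes <- function() c("running", "sitting", "grooming")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

abort_input <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_input(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    abort_input(sprintf("`%s` must be in [%s, %s] (got %s)",
                        name, lower, upper, x))
  if (integer && x != round(x))
    abort_input(sprintf("`%s` must be an integer (got %s)", name, x))
  invisible(x)
}

# Row-normalize a non-negative matrix; errors on all-zero rows.
normalize_rows <- function(m, what = "probability") {
  rs <- rowSums(m)
  bad <- which(rs <= 0 | !is.finite(rs))
  if (length(bad))
    abort_input(sprintf("all-zero %s row at frame %d", what, bad[1L]))
  sweep(m, 1L, rs, "/")
}
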