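#' Percentage with fixed rounding
#'
#' Computes `100 * x / n` rounded to `digits` decimals, the convention used
#' throughout the cohort summaries (one decimal) and signature composition
#' reports (integer percent).
#'
#' @param x Numerator count.
#' @param n Denominator count; must be positive.
#' @param digits Decimal places to round to.
#' @return Numeric percentage.
#' @examples
#' percent(39, 74)        # 52.7
#' percent(74, 155, 0)    # 48
#' @export
percent <- function(x, n, digits = 1) {
  if (length(n) != 1L || is.na(n) || n <= 0) {
    stop("`n` must be a single positive count", call. = FALSE)
  }
  round(100 * x / n, digits = digits)
}

# clamp into [lo, hi]; used to keep beta means inside the open unit interval
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' @keywords internal
assert_beta_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("`%s` contains missing values", name), call. = FALSE)
  }
  bad <- which(x < 0 | x > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "`%s` has value %.4g outside [0,1] at row %d (%s), column %d (%s)",
      name, x[bad[1, 1], bad[1, 2]],
      bad[1, 1], rownames(x)[bad[1, 1]] %||% "?",
      bad[1, 2], colnames(x)[bad[1, 2]] %||% "?"
    ), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stderr logging; warnings elsewhere are never silently swallowed
log_msg <- function(fmt, ...) message(sprintf(fmt, ...))
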