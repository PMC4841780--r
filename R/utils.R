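#' Round half away from zero
#'
#' Percentages reported by [summary_stats()] follow the convention used in
#' printed screen summaries: ties round away from zero rather than to even
#' (base \code{round()} uses banker's rounding).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

## Seeded RNG scoping: every stochastic operation takes a `seed` argument and
## restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
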