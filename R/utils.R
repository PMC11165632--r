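`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed fold enrichments use the
#' conventional half-up rule (e.g. 16.75 -> 16.8), so that rule is applied
#' wherever a value is reported at fixed decimal precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}
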