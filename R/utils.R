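#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all printed money and EV
#' totals in reports: ties go away from zero, unlike [round()]'s
#' round-half-to-even. Exact ties are subject to binary representation of
#' `x * 10^digits`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) is 0
#' round_half_up(2.675, 2)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # the sqrt(eps) nudge keeps decimal ties (e.g. 2.05 x an integer) from
  # falling a few ulps below .5 in binary and rounding down
  trunc(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / f
}

# Classed abort so callers can distinguish validation from usage errors.
ev_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "evcost_error"), ...)
}

ev_stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                       nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ev_abort(sprintf("`%s` must be a single finite number.", name),
             "evcost_error_type")
  }
  if (positive && x <= 0) {
    ev_abort(sprintf("`%s` must be > 0 (got %g).", name, x),
             "evcost_error_domain")
  }
  if (nonnegative && x < 0) {
    ev_abort(sprintf("`%s` must be >= 0 (got %g).", name, x),
             "evcost_error_domain")
  }
  invisible(x)
}

ev_require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ev_abort(
      sprintf("%s is missing required column(s): %s.",
              what, paste(missing, collapse = ", ")),
      "evcost_error_schema"
    )
  }
  invisible(df)
}

# Format money for the plain-text tables (2 decimals, thousands separators).
ev_format_money <- function(x, decimals = 2) {
  formatC(x, format = "f", digits = decimals, big.mark = ",")
}

ev_guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv",
    json = "json",
    yaml = ,
    yml = "yaml",
    ev_abort(
      sprintf("Cannot guess format from extension '.%s'; pass `format`.", ext),
      "evcost_error_schema"
    )
  )
}
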