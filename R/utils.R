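#' Round half-up to a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used for the displayed percentages
#' and odds ratios in pharmacovigilance tables.  Base [round()] uses
#' banker's rounding (round-half-even), which disagrees on exact halves.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.345, 2)  # 2.35, where round() gives 2.34
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # tiny epsilon guards against 1.005 being stored as 1.00499999...
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Truncate to a fixed number of decimals
#'
#' Drops decimal digits beyond `digits` without rounding.  Offered because
#' published safety tables are not always consistent about rounding mode
#' (some proportions are evidently truncated), and reproducing a printed
#' value can require matching the original convention.
#'
#' @inheritParams round_half_up
#' @return `x` truncated towards zero at `digits` decimals.
#' @export
trunc_digits <- function(x, digits = 2) {
  scale <- 10^digits
  trunc(x * scale + sign(x) * sqrt(.Machine$double.eps)) / scale
}

round_mode <- function(x, digits, mode = c("halfup", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "halfup") round_half_up(x, digits) else trunc_digits(x, digits)
}

#' Quarter label helpers
#'
#' FAERS publishes one file set per calendar quarter; the analysis window
#' is defined by quarter labels of the form `"2015Q1"`.
#'
#' @param from,to inclusive quarter labels.
#' @return `quarter_seq()`: character vector of consecutive quarter labels.
#' @examples
#' quarter_seq("2015Q1", "2015Q4")
#' @export
quarter_seq <- function(from, to) {
  stopifnot(is_quarter(from), is_quarter(to))
  a <- quarter_index(from)
  b <- quarter_index(to)
  if (a > b) stop("quarter window is not well-ordered: ", from, " > ", to)
  idx <- a:b
  paste0(idx %/% 4L, "Q", idx %% 4L + 1L)
}

is_quarter <- function(x) {
  is.character(x) & grepl("^[0-9]{4}Q[1-4]$", x)
}

quarter_index <- function(x) {
  4L * as.integer(substr(x, 1L, 4L)) + as.integer(substr(x, 6L, 6L)) - 1L
}

quarter_year <- function(x) as.integer(substr(x, 1L, 4L))

## canonical PT normalization: trim + case-fold; matching is exact after this
norm_pt <- function(x) tolower(trimws(x))
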