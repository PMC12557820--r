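# Shared helpers: FAERS-style dates, drug-name normalization, small checks.

#' Normalize a drug or term name for matching
#'
#' FAERS drug names and reaction terms are free text: matching is done on
#' the uppercased, trimmed form with internal whitespace collapsed.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Precision of a FAERS-style date string
#'
#' @param x character vector of dates written as `YYYYMMDD`, `YYYYMM`,
#'   `YYYY`, or empty/NA when unknown.
#' @return integer vector: 8, 6, 4 for the three precisions, 0 when the
#'   value is missing or not a date.
#' @export
date_precision <- function(x) {
  x <- trimws(as.character(x))
  out <- integer(length(x))
  ok <- !is.na(x) & grepl("^[0-9]+$", x)
  out[ok & nchar(x) == 8L] <- 8L
  out[ok & nchar(x) == 6L] <- 6L
  out[ok & nchar(x) == 4L] <- 4L
  out
}

#' Convert full-precision date strings to Date
#'
#' Partial (`YYYY`, `YYYYMM`) and missing values become `NA`: day-level
#' arithmetic is never performed on partial dates.
#'
#' @param x character vector of `YYYYMMDD` strings.
#' @return `Date` vector with `NA` where precision is below day level.
#' @export
as_date8 <- function(x) {
  x <- trimws(as.character(x))
  full <- date_precision(x) == 8L
  out <- rep(as.Date(NA), length(x))
  if (any(full)) out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

# Numeric sort key for fda_dt: unparseable/partial dates sort earliest so a
# dated report always survives over an undated rival.
fda_dt_key <- function(x) {
  k <- suppressWarnings(as.numeric(x))
  k[date_precision(x) != 8L] <- -Inf
  k[is.na(k)] <- -Inf
  k
}

# primaryid comparison: numeric when both sides parse as numbers (FAERS ids
# are numeric strings of varying length), lexicographic otherwise.
primaryid_order_keys <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  list(num = ifelse(is.na(num), -Inf, num), chr = as.character(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
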