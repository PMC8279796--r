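#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

# Day-resolution intervals -----------------------------------------------
#
# Every TQL expression evaluates, per patient, to an *interval set*: a set of
# half-open day intervals [start, end) with 0-based day indices counted from
# the epoch 1900-01-01.  A point event on day d is [d, d + 1).  Interval sets
# are kept in canonical form: a 2-column integer matrix, rows sorted by
# start, pairwise disjoint and non-adjacent (adjacent intervals are merged,
# which is unambiguous under the half-open convention).

#' Epoch used for day indexing
#'
#' Day 0 is 1900-01-01; all event timing is stored as integer days since this
#' epoch.
#' @return A `Date` of length 1.
#' @export
tql_epoch <- function() as.Date("1900-01-01")

#' Convert calendar dates to day indices and back
#'
#' @param x A `Date` vector, or anything `as.Date()` accepts (for
#'   `date_to_day`); an integer day-index vector (for `day_to_date`).
#' @return Integer day indices since [tql_epoch()], or the corresponding
#'   `Date`s.
#' @examples
#' date_to_day("1900-01-02")  # 1
#' day_to_date(0L)            # "1900-01-01"
#' @export
date_to_day <- function(x) as.integer(as.Date(x) - tql_epoch())

#' @rdname date_to_day
#' @export
day_to_date <- function(x) tql_epoch() + as.integer(x)

#' The empty interval set
#'
#' @return A 0-row canonical interval-set matrix.
#' @export
empty_iset <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

iset_matrix <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (is.null(dim(m))) m <- matrix(m, ncol = 2L, dimnames = list(NULL, c("start", "end")))
  m
}

#' Coalesce raw intervals into a canonical interval set
#'
#' Accepts unsorted, overlapping and adjacent half-open intervals and returns
#' the canonical form: sorted by start, pairwise disjoint, non-adjacent.  The
#' set of covered days is preserved exactly.
#'
#' @param start,end Integer vectors of equal length; each pair must satisfy
#'   `start < end`.
#' @return A canonical interval-set matrix.
#' @examples
#' coalesce_intervals(c(0, 5), c(10, 15))  # [0, 15)
#' coalesce_intervals(c(0, 5), c(5, 9))    # [0, 9): adjacency merges
#' @export
coalesce_intervals <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length", call. = FALSE)
  }
  if (length(start) == 0L) return(empty_iset())
  if (anyNA(start) || anyNA(end)) stop("NA interval bound", call. = FALSE)
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("degenerate interval [%d, %d): start must be < end",
                 start[bad], end[bad]), call. = FALSE)
  }
  o <- order(start, end)
  s <- start[o]; e <- cummax(end[o])
  n <- length(s)
  # a new run starts where this start exceeds the running max end so far
  new_run <- c(TRUE, s[-1L] > e[-n])
  last_of_run <- c(which(new_run[-1L]), n)
  iset_matrix(s[new_run], e[last_of_run])
}

#' Build an interval set
#'
#' Thin wrapper around [coalesce_intervals()] for literal construction.
#' @inheritParams coalesce_intervals
#' @return A canonical interval-set matrix.
#' @export
interval_set <- function(start = integer(0), end = integer(0)) {
  coalesce_intervals(start, end)
}

is_empty_iset <- function(x) nrow(x) == 0L

# clip a canonical set to one interval [lo, hi); result stays canonical
iset_clip <- function(x, lo, hi) {
  if (nrow(x) == 0L || lo >= hi) return(empty_iset())
  s <- pmax(x[, 1L], lo)
  e <- pmin(x[, 2L], hi)
  keep <- s < e
  iset_matrix(s[keep], e[keep])
}

# total number of days covered
iset_days_covered <- function(x) {
  if (nrow(x) == 0L) return(0L)
  sum(x[, 2L] - x[, 1L])
}

# expand to the sorted vector of covered integer days (small spans only)
iset_days <- function(x) {
  if (nrow(x) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(x)), function(i) seq.int(x[i, 1L], x[i, 2L] - 1L)),
         use.names = FALSE)
}

#' Present an interval set as a data frame of dates
#'
#' @param x A canonical interval-set matrix.
#' @return A data frame with `start`, `end` (day indices) and `start_date`,
#'   `end_date` (`end_date` is the exclusive bound).
#' @export
iset_as_dates <- function(x) {
  data.frame(start = x[, 1L], end = x[, 2L],
             start_date = day_to_date(x[, 1L]),
             end_date = day_to_date(x[, 2L]))
}
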