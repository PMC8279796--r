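# Temporal algebra ------------------------------------------------------
#
# Pure per-patient semantics of the TQL temporal commands.  All operands and
# results are canonical interval-set matrices (see intervals.R).  These
# functions know nothing about patients or features; the engine supplies the
# operand sets and, where needed, the patient's observation span.

#' Sequence window modifier
#'
#' A window attached to a SEQUENCE command.  `mode = "presence"` (written
#' `+(lo, hi)` in TQL) requires a non-starred event start within `[lo, hi]`
#' days of the starred interval's start; `mode = "absence"` (`-(lo, hi)`)
#' requires that none occurs there.  Offsets are signed days (negative =
#' before the starred event); both boundaries are inclusive.  TQL durations
#' convert at 1 DAY = 1, 1 MONTH = 30, 1 YEAR = 365 days; MAX is unbounded.
#'
#' @param mode `"presence"` or `"absence"`.
#' @param lo,hi Signed day offsets, `lo <= hi`; `-Inf`/`Inf` allowed.
#' @return A `tql_window` list.
#' @export
window_modifier <- function(mode = c("presence", "absence"), lo, hi) {
  mode <- match.arg(mode)
  if (lo > hi) stop("window lo must be <= hi", call. = FALSE)
  structure(list(mode = mode, lo = lo, hi = hi), class = "tql_window")
}

#' Temporal union
#'
#' Time intervals where the patient had a record of *any* operand: the
#' coalesced union of the operand sets.
#'
#' @param sets A non-empty list of canonical interval-set matrices.
#' @return A canonical interval-set matrix.
#' @export
t_union <- function(sets) {
  stopifnot(length(sets) >= 1L)
  m <- do.call(rbind, sets)
  if (is.null(m) || nrow(m) == 0L) return(empty_iset())
  coalesce_intervals(m[, 1L], m[, 2L])
}

iset_intersect2 <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(empty_iset())
  i <- 1L; j <- 1L
  out_s <- integer(0); out_e <- integer(0)
  while (i <= na && j <= nb) {
    s <- max(a[i, 1L], b[j, 1L])
    e <- min(a[i, 2L], b[j, 2L])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a[i, 2L] < b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  iset_matrix(out_s, out_e)
}

#' Temporal intersection
#'
#' Time intervals where the patient had a record of *all* operands at the
#' same time.  Empty if any operand is empty.
#'
#' @inheritParams t_union
#' @return A canonical interval-set matrix.
#' @export
t_intersect <- function(sets) {
  stopifnot(length(sets) >= 1L)
  Reduce(iset_intersect2, sets)
}

#' Timeline inversion
#'
#' The complement of `x` within the patient's observation span: the time
#' where it was *not* true.  `x` is clipped to the span first, so double
#' inversion returns `x` restricted to the span.
#'
#' @param x A canonical interval-set matrix.
#' @param span Length-2 integer vector `c(start, end)`, the observation
#'   period as a half-open interval.
#' @return A canonical interval-set matrix.
#' @export
t_invert <- function(x, span) {
  lo <- span[1L]; hi <- span[2L]
  if (lo >= hi) return(empty_iset())
  x <- iset_clip(x, lo, hi)
  if (nrow(x) == 0L) return(iset_matrix(lo, hi))
  bounds_s <- c(lo, x[, 2L])
  bounds_e <- c(x[, 1L], hi)
  keep <- bounds_s < bounds_e
  iset_matrix(bounds_s[keep], bounds_e[keep])
}

#' Temporal sequence of two event streams
#'
#' Implements SEQUENCE: two operand interval sets, one of which is *starred*
#' (its intervals are the ones returned).  Without a window, a starred
#' interval qualifies when a non-starred interval starts strictly before it
#' (`star = "second"`) or strictly after it (`star = "first"`); same-day
#' starts do not qualify.  With a window the window test replaces the
#' ordering test: the window is anchored at the starred interval's start day
#' and inspects non-starred start days (see [window_modifier()]).
#'
#' @param a,b Canonical interval-set matrices (first and second operand).
#' @param star `"first"` or `"second"`: which operand's intervals to return.
#' @param window Optional `tql_window`.
#' @return A canonical interval-set matrix: a subset of the starred
#'   operand's intervals.
#' @export
t_sequence <- function(a, b, star = c("second", "first"), window = NULL) {
  star <- match.arg(star)
  if (star == "second") { starred <- b; other <- a } else { starred <- a; other <- b }
  if (nrow(starred) == 0L) return(empty_iset())
  os <- other[, 1L]
  ss <- starred[, 1L]
  if (is.null(window)) {
    if (length(os) == 0L) return(empty_iset())
    ok <- if (star == "second") {
      vapply(ss, function(s) any(os < s), logical(1L))
    } else {
      vapply(ss, function(s) any(os > s), logical(1L))
    }
  } else {
    hit <- vapply(ss, function(s) any(os >= s + window$lo & os <= s + window$hi),
                  logical(1L))
    ok <- if (window$mode == "presence") hit else !hit
  }
  starred[ok, , drop = FALSE]
}

#' Occurrence-count filter
#'
#' Returns `x` unchanged when the number of its (coalesced, disjoint)
#' intervals lies in `[min_n, max_n]`, otherwise the empty set.  Counting is
#' of canonical intervals, not raw source rows: several same-day records of
#' a code contribute one interval.
#'
#' @param x A canonical interval-set matrix.
#' @param min_n Non-negative integer.
#' @param max_n Integer or `Inf` (the MAX sentinel).
#' @return `x` or the empty set.
#' @export
t_count <- function(x, min_n, max_n = Inf) {
  if (min_n < 0) stop("COUNT min must be >= 0", call. = FALSE)
  if (min_n > max_n) stop("COUNT min must be <= max", call. = FALSE)
  n <- nrow(x)
  if (n >= min_n && n <= max_n) x else empty_iset()
}

#' Earliest interval
#'
#' FIRST MENTION: the single earliest-starting interval of `x`; empty in,
#' empty out.
#'
#' @param x A canonical interval-set matrix.
#' @return A canonical interval-set matrix with at most one row.
#' @export
t_first_mention <- function(x) {
  if (nrow(x) == 0L) return(empty_iset())
  x[1L, , drop = FALSE]
}

#' Timeline before any occurrence
#'
#' NO HISTORY OF: the whole observation span when `x` is empty, otherwise
#' the part of the span strictly before the first occurrence (empty when the
#' first occurrence starts at or before the span start).
#'
#' @inheritParams t_invert
#' @return A canonical interval-set matrix.
#' @export
t_no_history_of <- function(x, span) {
  lo <- span[1L]; hi <- span[2L]
  if (lo >= hi) return(empty_iset())
  if (nrow(x) == 0L) return(iset_matrix(lo, hi))
  first <- x[1L, 1L]
  if (first <= lo) return(empty_iset())
  iset_matrix(lo, min(first, hi))
}

#' Absence over the whole record
#'
#' NEVER HAD: the whole observation span when `x` is empty, otherwise the
#' empty set.
#'
#' @inheritParams t_invert
#' @return A canonical interval-set matrix.
#' @export
t_never_had <- function(x, span) {
  lo <- span[1L]; hi <- span[2L]
  if (lo >= hi || nrow(x) > 0L) return(empty_iset())
  iset_matrix(lo, hi)
}
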