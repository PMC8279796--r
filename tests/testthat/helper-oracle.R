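# Independent day-set interpreter.
#
# An interval set over a patient's observation span is fully characterized
# by the set of integer days it covers.  This interpreter evaluates a query
# AST to a logical day-membership vector over the span, using plain loops
# and rle() runs -- deliberately a different representation and code path
# from the engine's interval matrices -- and is the reference the engine is
# checked against.

ds_eval <- function(expr, p, defs = list(),
                    memo = new.env(parent = emptyenv()),
                    original_only = FALSE) {
  lo <- p$span[1L]
  n <- p$span[2L] - lo
  empty <- function() rep(FALSE, n)
  full <- function() rep(TRUE, n)
  mark_rows <- function(rows) {
    v <- empty()
    for (i in rows) {
      a <- max(p$events$start[i], lo)
      b <- min(p$events$end[i], p$span[2L])
      if (a < b) v[(a - lo + 1L):(b - lo)] <- TRUE
    }
    v
  }
  runs <- function(v) {
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    cbind(s = s[r$values], e = e[r$values])
  }
  rec <- function(e, orig = original_only) {
    switch(e$op,
      selector = {
        if (e$ns %in% c("GENDER", "RACE")) {
          val <- if (e$ns == "GENDER") p$gender else p$race
          if (tolower(val) == tolower(e$code)) full() else empty()
        } else {
          key <- paste0(e$ns, ":", e$code)
          mark_rows(which(p$events$key == key & (!orig | p$events$original)))
        }
      },
      labs = mark_rows(which(p$events$key == paste0("LOINC:", e$code) &
                               !is.na(p$events$value) &
                               p$events$value >= e$lo & p$events$value <= e$hi)),
      text = {
        ev <- p$events
        f <- switch(e$flag,
                    plain = !ev$negated & !ev$family_history,
                    negated = ev$negated,
                    family_history = ev$family_history)
        mark_rows(which(ev$key == paste0("TEXT:", e$phrase) & f))
      },
      age = {
        v <- empty()
        a <- max(p$birth_day + e$lo, lo)
        b <- if (is.infinite(e$hi)) p$span[2L] else min(p$birth_day + e$hi, p$span[2L])
        if (a < b) v[(a - lo + 1L):(b - lo)] <- TRUE
        v
      },
      year = {
        v <- empty()
        a <- max(date_to_day(sprintf("%04d-01-01", e$lo)), lo)
        b <- min(date_to_day(sprintf("%04d-01-01", e$hi + 1L)), p$span[2L])
        if (a < b) v[(a - lo + 1L):(b - lo)] <- TRUE
        v
      },
      varref = {
        if (!exists(e$name, memo, inherits = FALSE)) {
          assign(e$name, rec(defs[[e$name]]), memo)
        }
        get(e$name, memo, inherits = FALSE)
      },
      union = Reduce(`|`, lapply(e$args, rec)),
      intersect = Reduce(`&`, lapply(e$args, rec)),
      invert = !rec(e$arg),
      and = if (all(vapply(e$args, function(a) any(rec(a)), logical(1L)))) full() else empty(),
      or = if (any(vapply(e$args, function(a) any(rec(a)), logical(1L)))) full() else empty(),
      not = if (any(vapply(e$args, function(a) any(rec(a)), logical(1L)))) empty() else full(),
      diff = if (any(rec(e$args[[2L]]))) empty() else rec(e$args[[1L]]),
      count = {
        v <- rec(e$arg)
        k <- nrow(runs(v))
        if (k >= e$min && k <= e$max) v else empty()
      },
      first_mention = {
        v <- rec(e$arg)
        r <- runs(v)
        w <- empty()
        if (nrow(r)) w[r[1L, 1L]:r[1L, 2L]] <- TRUE
        w
      },
      no_history_of = {
        first <- which(rec(e$arg))[1L]
        w <- empty()
        if (is.na(first)) w <- full() else if (first > 1L) w[1L:(first - 1L)] <- TRUE
        w
      },
      never_had = if (any(rec(e$arg))) empty() else full(),
      original = rec(e$arg, orig = TRUE),
      sequence = {
        va <- rec(e$first)
        vb <- rec(e$second)
        if (e$star == "second") { sv <- vb; ov <- va } else { sv <- va; ov <- vb }
        rs <- runs(sv)
        ro <- runs(ov)
        ostarts <- lo + ro[, 1L] - 1L
        w <- empty()
        for (i in seq_len(nrow(rs))) {
          sstart <- lo + rs[i, 1L] - 1L
          ok <- if (is.null(e$window)) {
            if (e$star == "second") any(ostarts < sstart) else any(ostarts > sstart)
          } else {
            hit <- any(ostarts >= sstart + e$window$lo &
                         ostarts <= sstart + e$window$hi)
            if (e$window$mode == "presence") hit else !hit
          }
          if (ok) w[rs[i, 1L]:rs[i, 2L]] <- TRUE
        }
        w
      },
      export = rec(e$cohort),
      stop("oracle: unknown op ", e$op))
  }
  rec(expr)
}

# interval matrix -> day-membership vector over a span
iset_to_dayvec <- function(m, span) {
  lo <- span[1L]
  v <- rep(FALSE, span[2L] - lo)
  for (i in seq_len(nrow(m))) {
    a <- max(m[i, 1L], lo)
    b <- min(m[i, 2L], span[2L])
    if (a < b) v[(a - lo + 1L):(b - lo)] <- TRUE
  }
  v
}

# day-membership vector of a raw (uncoalesced) interval list over [0, n)
raw_dayvec <- function(start, end, n) {
  v <- rep(FALSE, n)
  for (i in seq_along(start)) {
    a <- max(start[i], 0L)
    b <- min(end[i], n)
    if (a < b) v[(a + 1L):b] <- TRUE
  }
  v
}
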