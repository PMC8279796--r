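iv <- function(s, e) interval_set(s, e)

test_that("union and intersection handle the attested edge cases", {
  expect_identical(t_union(list(iv(0, 5), empty_iset())), iv(0, 5))
  expect_identical(t_union(list(iv(0, 5), iv(3, 8))), iv(0, 8))
  # half-open: touching intervals do not intersect
  expect_identical(t_intersect(list(iv(0, 5), iv(5, 9))), empty_iset())
  expect_identical(t_intersect(list(iv(0, 10), iv(3, 6))), iv(3, 6))
  expect_identical(t_intersect(list(iv(0, 10), empty_iset())), empty_iset())
})

test_that("inversion complements within the span and is an involution", {
  span <- c(0L, 100L)
  expect_identical(t_invert(empty_iset(), span), iv(0, 100))
  expect_identical(t_invert(iv(0, 100), span), empty_iset())
  set.seed(11)
  for (rep in 1:200) {
    x <- rand_iset(120L)
    expect_identical(iset_to_dayvec(t_invert(x, span), span),
                     !iset_to_dayvec(x, span))
    expect_identical(t_invert(t_invert(x, span), span),
                     cohortql:::iset_clip(x, 0L, 100L))
  }
})

test_that("sequence matches ordering and window semantics on known cases", {
  # event in b within 3 months (90 days) after event in a
  expect_identical(
    t_sequence(iv(0, 1), iv(90, 91), star = "second",
               window = window_modifier("presence", -90, 0)),
    iv(90, 91))
  # order violated without a window
  expect_identical(t_sequence(iv(10, 11), iv(5, 6), star = "second"),
                   empty_iset())
  # same-day events do not satisfy strict sequencing
  expect_identical(t_sequence(iv(10, 11), iv(10, 11), star = "second"),
                   empty_iset())
  # absence window: b kept only when no a-event in the window
  expect_identical(
    t_sequence(iv(50, 51), iv(c(60, 300), c(61, 301)), star = "second",
               window = window_modifier("absence", -30, 0)),
    iv(300, 301))
  # star on the first operand returns a-intervals followed by b
  expect_identical(t_sequence(iv(c(0, 50), c(1, 51)), iv(20, 21), star = "first"),
                   iv(0, 1))
})

test_that("sequence agrees with pairwise enumeration on random cases", {
  set.seed(21)
  for (rep in 1:500) {
    a <- rand_iset(150L, 4L)
    b <- rand_iset(150L, 4L)
    star <- sample(c("first", "second"), 1L)
    w <- if (runif(1) < 0.5) NULL else {
      lo <- sample(-120:60, 1L)
      window_modifier(sample(c("presence", "absence"), 1L), lo,
                      lo + sample(0:90, 1L))
    }
    got <- t_sequence(a, b, star, w)
    starred <- if (star == "second") b else a
    other <- if (star == "second") a else b
    keep <- vapply(seq_len(nrow(starred)), function(i) {
      s <- starred[i, 1L]
      os <- other[, 1L]
      if (is.null(w)) {
        if (star == "second") any(os < s) else any(os > s)
      } else {
        hit <- any(os >= s + w$lo & os <= s + w$hi)
        if (w$mode == "presence") hit else !hit
      }
    }, logical(1L))
    expect_identical(got, starred[keep, , drop = FALSE])
    # starred-subset property
    expect_true(all(got[, 1L] %in% starred[, 1L]))
  }
})

test_that("count filters by the number of disjoint intervals", {
  x <- iv(c(5, 9), c(6, 10))
  expect_identical(t_count(x, 2, Inf), x)
  expect_identical(t_count(iv(5, 6), 2, Inf), empty_iset())
  # same-day (coalesced) records count once
  expect_identical(t_count(interval_set(c(5, 5), c(6, 6)), 2, Inf), empty_iset())
  expect_error(t_count(x, 3, 2), "min")
  set.seed(31)
  for (rep in 1:200) {
    x <- rand_iset()
    mn <- sample(0:4, 1L)
    mx <- mn + sample(0:4, 1L)
    expect_identical(t_count(x, mn, mx),
                     if (nrow(x) >= mn && nrow(x) <= mx) x else empty_iset())
  }
})

test_that("first mention picks the earliest interval", {
  expect_identical(t_first_mention(iv(c(5, 9), c(6, 10))), iv(5, 6))
  expect_identical(t_first_mention(empty_iset()), empty_iset())
  set.seed(41)
  for (rep in 1:100) {
    x <- rand_iset()
    got <- t_first_mention(x)
    if (nrow(x) == 0L) expect_identical(got, empty_iset())
    else expect_identical(unname(got[1L, 1L]), min(x[, 1L]))
  }
})

test_that("no-history-of returns the timeline prefix before first occurrence", {
  span <- c(0L, 100L)
  expect_identical(t_no_history_of(empty_iset(), span), iv(0, 100))
  expect_identical(t_no_history_of(iv(40, 41), span), iv(0, 40))
  expect_identical(t_no_history_of(iv(0, 1), span), empty_iset())
  # never-had is all-or-nothing
  expect_identical(t_never_had(empty_iset(), span), iv(0, 100))
  expect_identical(t_never_had(iv(40, 41), span), empty_iset())
})

test_that("no-history-of never overlaps the argument (unless it starts pre-span)", {
  span <- c(10L, 200L)
  set.seed(51)
  for (rep in 1:300) {
    x <- rand_iset(180L)
    nh <- t_no_history_of(x, span)
    if (nrow(x) && x[1L, 1L] >= span[1L]) {
      expect_identical(t_intersect(list(nh, x)), empty_iset())
    }
    # equivalence with never-had when empty or pre-span
    if (nrow(x) == 0L || x[1L, 1L] <= span[1L]) {
      expect_identical(nh, t_never_had(x, span))
    }
  }
})

test_that("union/intersect laws hold on random operands", {
  set.seed(61)
  span <- c(0L, 250L)
  for (rep in 1:300) {
    a <- rand_iset(); b <- rand_iset(); c <- rand_iset()
    expect_identical(t_union(list(a, b)), t_union(list(b, a)))
    expect_identical(t_intersect(list(a, b)), t_intersect(list(b, a)))
    expect_identical(t_union(list(a, t_union(list(b, c)))),
                     t_union(list(t_union(list(a, b)), c)))
    expect_identical(t_intersect(list(a, t_intersect(list(b, c)))),
                     t_intersect(list(t_intersect(list(a, b)), c)))
    expect_identical(t_union(list(a, a)), a)
    expect_identical(t_intersect(list(a, a)), a)
    # De Morgan within the span
    expect_identical(t_invert(t_union(list(a, b)), span),
                     t_intersect(list(t_invert(a, span), t_invert(b, span))))
    expect_identical(t_invert(t_intersect(list(a, b)), span),
                     t_union(list(t_invert(a, span), t_invert(b, span))))
  }
})

test_that("all algebra ops agree with the day-set bitmap oracle", {
  set.seed(71)
  span <- c(0L, 250L)
  for (rep in 1:300) {
    a <- rand_iset(); b <- rand_iset()
    va <- iset_to_dayvec(a, span); vb <- iset_to_dayvec(b, span)
    expect_identical(iset_to_dayvec(t_union(list(a, b)), span), va | vb)
    expect_identical(iset_to_dayvec(t_intersect(list(a, b)), span), va & vb)
    expect_identical(iset_to_dayvec(t_invert(a, span), span), !va)
  }
})
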