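# Random fixtures for the property suites (all built in code, fixed seeds
# set by the calling tests).

rand_iset <- function(max_day = 200L, max_k = 6L) {
  k <- sample(0:max_k, 1L)
  if (k == 0L) return(empty_iset())
  s <- sample.int(max_day, k, replace = TRUE) - 1L
  len <- sample.int(30L, k, replace = TRUE)
  interval_set(s, s + len)
}

rand_raw_intervals <- function(k, max_day = 200L) {
  s <- sample.int(max_day, k, replace = TRUE) - 1L
  list(start = s, end = s + sample.int(30L, k, replace = TRUE))
}

TEST_VOCAB <- c("ICD9:250.00", "ICD9:250.02", "ICD9:434.91", "ICD9:401.9",
                "ICD10:E11.9", "CPT:99213", "RX:310490", "RX:161",
                "TEXT:fever", "GENDER:male", "RACE:white")

rand_selector_node <- function(vocab = TEST_VOCAB) {
  k <- sample(vocab, 1L)
  list(op = "selector", ns = sub(":.*$", "", k), code = sub("^[^:]*:", "", k))
}

rand_leaf <- function(vocab = TEST_VOCAB) {
  r <- runif(1L)
  if (r < 0.65) {
    rand_selector_node(vocab)
  } else if (r < 0.75) {
    list(op = "age", lo = sample(0:30000, 1L), hi = Inf)
  } else if (r < 0.85) {
    list(op = "labs", code = "2160-0", lo = round(runif(1L, 0, 1), 2), hi = Inf)
  } else if (r < 0.93) {
    list(op = "original", arg = rand_selector_node(vocab))
  } else {
    list(op = "text", phrase = "fever",
         flag = sample(c("plain", "negated", "family_history"), 1L))
  }
}

rand_ast <- function(depth = 2L, vocab = TEST_VOCAB) {
  if (depth <= 0L || runif(1L) < 0.3) return(rand_leaf(vocab))
  op <- sample(c("union", "intersect", "and", "or", "not", "invert",
                 "sequence", "count", "first_mention", "no_history_of",
                 "never_had", "diff"), 1L)
  mk <- function() rand_ast(depth - 1L, vocab)
  switch(op,
    union = , intersect = , and = , or = , not =
      list(op = op, args = lapply(seq_len(sample(2:3, 1L)), function(i) mk())),
    diff = list(op = "diff", args = list(mk(), mk())),
    invert = , first_mention = , no_history_of = , never_had =
      list(op = op, arg = mk()),
    count = list(op = "count", arg = mk(), min = sample(0:3, 1L),
                 max = sample(c(3:6, Inf), 1L)),
    sequence = {
      w <- if (runif(1L) < 0.5) NULL else {
        lo <- sample(-400:100, 1L)
        window_modifier(sample(c("presence", "absence"), 1L),
                        lo, lo + sample(0:300, 1L))
      }
      list(op = "sequence", first = mk(), second = mk(),
           star = sample(c("first", "second"), 1L), window = w)
    })
}

# one random query over the core commands, as TQL source (the shape of the
# randomized performance-experiment queries: parameters drawn from
# ICD9/ICD10/CPT/RX)
rand_core_query <- function(vocab) {
  sel <- function() {
    k <- sample(vocab, 1L)
    sprintf("%s=\"%s\"", sub(":.*$", "", k), sub("^[^:]*:", "", k))
  }
  switch(sample(c("or", "union", "and", "intersect", "sequence"), 1L),
    or = sprintf("OR(%s, %s, %s, %s)", sel(), sel(), sel(), sel()),
    union = sprintf("UNION(%s, %s, %s, %s)", sel(), sel(), sel(), sel()),
    and = sprintf("AND(%s, %s)", sel(), sel()),
    intersect = sprintf("INTERSECT(%s, %s)", sel(), sel()),
    sequence = sprintf("SEQUENCE(%s,%s*)", sel(), sel()))
}

# minimal OMOP directory with one patient / one stroke code
write_minimal_omop <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("person_id,year_of_birth,month_of_birth,day_of_birth,gender_source_value,race_source_value",
               "p1,1950,6,15,male,white"),
             file.path(dir, "person.csv"))
  writeLines(c("observation_period_id,person_id,observation_period_start_date,observation_period_end_date",
               "1,p1,2010-01-01,2019-12-31"),
             file.path(dir, "observation_period.csv"))
  writeLines(c("condition_occurrence_id,person_id,condition_start_date,condition_source_value",
               "1,p1,2015-03-02,ICD9:434.91"),
             file.path(dir, "condition_occurrence.csv"))
  invisible(dir)
}

expect_same_matches <- function(a, b) {
  expect_identical(a$matches, b$matches)
}
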