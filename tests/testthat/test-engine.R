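onts <- default_ontologies()

mk_patient <- function(id = "p1", birth = "1940-01-01", gender = "female",
                       span = c("2010-01-01", "2019-12-31"), events = NULL,
                       expand = TRUE) {
  p <- new_patient(id, date_to_day(birth), gender, "white",
                   c(date_to_day(span[1L]), date_to_day(span[2L]) + 1L),
                   if (is.null(events)) empty_events() else events)
  if (expand) p <- expand_events(p, onts[c("ICD9", "ICD10")], onts$drug_map)
  p
}

test_that("trial-inclusion style evaluation combines selectors, age and history", {
  # female, 72 at diagnosis, carcinoma in situ with no prior invasive cancer
  d <- date_to_day("2015-06-01")
  p <- mk_patient(events = events_frame("ICD9:233.0", d))
  prog <- parse_tql(tql_example("breast_ca_trial"))
  m <- evaluate_patient(prog$final, p, prog$vars)
  expect_identical(unname(m), matrix(c(d, d + 1L), 1L))
  # a prior invasive-cancer code excludes the patient
  p2 <- mk_patient(events = rbind(events_frame("ICD9:233.0", d),
                                  events_frame("ICD9:174", d - 200L)))
  expect_identical(nrow(evaluate_patient(prog$final, p2, prog$vars)), 0L)
  # ... including one recorded as a child code, via hierarchical expansion
  p3 <- mk_patient(events = rbind(events_frame("ICD9:233.0", d),
                                  events_frame("ICD9:174.9", d - 200L)))
  expect_identical(nrow(evaluate_patient(prog$final, p3, prog$vars)), 0L)
  # an invasive code *after* the in-situ diagnosis does not
  p4 <- mk_patient(events = rbind(events_frame("ICD9:233.0", d),
                                  events_frame("ICD9:174", d + 200L)))
  expect_identical(nrow(evaluate_patient(prog$final, p4, prog$vars)), 1L)
})

test_that("an event-free, non-matching patient evaluates to empty everywhere", {
  p <- mk_patient(gender = "male", events = NULL)
  prog <- parse_tql(tql_example("breast_ca_trial"))
  expect_identical(nrow(evaluate_patient(prog$final, p, prog$vars)), 0L)
})

test_that("boolean commands return the span or nothing; DIFF keeps first operand", {
  d <- date_to_day("2015-06-01")
  p <- mk_patient(events = events_frame("ICD9:233.0", d))
  span_m <- matrix(p$span, 1L)
  expect_identical(unname(evaluate_patient(parse_tql('AND(ICD9="233.0", GENDER="female")')$final, p)),
                   span_m)
  expect_identical(nrow(evaluate_patient(parse_tql('AND(ICD9="233.0", ICD9="174")')$final, p)), 0L)
  expect_identical(unname(evaluate_patient(parse_tql('OR(ICD9="174", ICD9="233.0")')$final, p)),
                   span_m)
  expect_identical(unname(evaluate_patient(parse_tql('NOT(ICD9="174")')$final, p)),
                   span_m)
  # DIFF: first operand's intervals survive iff second is empty
  expect_identical(unname(evaluate_patient(parse_tql('DIFF(ICD9="233.0", ICD9="174")')$final, p)),
                   matrix(c(d, d + 1L), 1L))
  expect_identical(nrow(evaluate_patient(parse_tql('DIFF(ICD9="174", ICD9="233.0")')$final, p)), 0L)
})

test_that("ORIGINAL restricts to source-coded events", {
  d <- date_to_day("2014-02-03")
  p <- mk_patient(events = events_frame("ICD9:250.02", d))
  for (code in c("250.02", "250.0", "250")) {
    m <- evaluate_patient(parse_tql(sprintf('ICD9="%s"', code))$final, p)
    expect_identical(unname(m), matrix(c(d, d + 1L), 1L), label = code)
  }
  expect_identical(nrow(evaluate_patient(parse_tql('ORIGINAL(ICD9="250.0")')$final, p)), 0L)
  expect_identical(nrow(evaluate_patient(parse_tql('ORIGINAL(ICD9="250.02")')$final, p)), 1L)
})

test_that("candidate sets are sound and exact for pure conjunctive selector queries", {
  store <- random_patient_store(300L, seed = 17L, expand = TRUE)
  q <- 'INTERSECT(GENDER="male", ICD9="250.00", ICD9="434.91")'
  prog <- parse_tql(q)
  cand <- candidate_set(prog$final, store)
  want <- Reduce(intersect, list(index_lookup(store, "GENDER:male"),
                                 index_lookup(store, "ICD9:250.00"),
                                 index_lookup(store, "ICD9:434.91")))
  expect_setequal(cand, want)
  res <- execute_query(prog, store)
  expect_true(all(matched_ids(res) %in% cand))
  # unknown code: empty candidates, empty result
  expect_identical(candidate_set(parse_tql('ICD9="000.0"')$final, store),
                   character(0))
  expect_length(execute_query('ICD9="000.0"', store)$matches, 0L)
})

test_that("indexed execution equals full scan on random queries (soundness suite)", {
  store <- random_patient_store(200L, seed = 23L)
  vocab <- grep("^(ICD9|ICD10|CPT|RX):", index_keys(store), value = TRUE)
  set.seed(29)
  for (rep in 1:40) {
    q <- rand_core_query(vocab)
    a <- execute_query(q, store)
    b <- execute_query(q, store, use_index = FALSE)
    expect_same_matches(a, b)
    prog <- parse_tql(q)
    cand <- candidate_set(prog$final, store)
    if (!is.null(cand)) expect_true(all(matched_ids(a) %in% cand))
  }
})

test_that("the engine agrees with the day-set interpreter on random ASTs", {
  store <- random_patient_store(15L, seed = 37L, expand = TRUE)
  set.seed(43)
  for (rep in 1:300) {
    ast <- rand_ast(depth = 2L)
    for (p in store$patients[sample(length(store$patients), 3L)]) {
      got <- evaluate_patient(ast, p)
      want <- ds_eval(ast, p)
      expect_identical(iset_to_dayvec(got, p$span), want)
    }
  }
})

test_that("variables are memoized per patient and evaluated in definition order", {
  d <- date_to_day("2013-05-05")
  p <- mk_patient(events = events_frame("ICD9:233.0", d))
  prog <- parse_tql('vara= ICD9="233.0"
varb= FIRST MENTION($a)
INTERSECT($a,$b)')
  bindings <- new.env(parent = emptyenv())
  m <- evaluate_patient(prog$final, p, prog$vars, bindings)
  expect_identical(unname(m), matrix(c(d, d + 1L), 1L))
  expect_setequal(ls(bindings), c("a", "b"))
})

test_that("repeated execution is deterministic", {
  store <- random_patient_store(100L, seed = 53L)
  q <- 'SEQUENCE(ICD9="250.00",ICD9="434.91"*)+(-90 DAYS, 0 DAYS)'
  r1 <- execute_query(q, store)
  r2 <- execute_query(q, store)
  expect_identical(r1$matches, r2$matches)
  fs <- first_satisfaction(r1)
  expect_identical(fs$first_day,
                   vapply(r1$matches, function(m) m[1L, 1L], integer(1L),
                          USE.NAMES = FALSE))
})

test_that("planting a code makes ancestor queries match; ORIGINAL removes them", {
  store <- build_store(list(mk_patient(id = "x1",
                                       events = events_frame("ICD9:250.02",
                                                             date_to_day("2012-01-05")))))
  for (code in c("250.02", "250.0", "250")) {
    expect_identical(matched_ids(execute_query(sprintf('ICD9="%s"', code), store)),
                     "x1", label = code)
  }
  expect_length(execute_query('ORIGINAL(ICD9="250.0")', store)$matches, 0L)
  expect_identical(matched_ids(execute_query('ORIGINAL(ICD9="250.02")', store)),
                   "x1")
})
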