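onts <- default_ontologies()

demo_store <- function() {
  mk <- function(id, birth, gender, race, code_day) {
    new_patient(id, date_to_day(birth), gender, race,
                c(date_to_day("2010-01-01"), date_to_day("2020-01-01")),
                events_frame("ICD9:233.0", date_to_day(code_day)))
  }
  build_store(list(
    mk("a1", "1941-01-01", "female", "white", "2015-01-01"),  # 74 at match
    mk("a2", "1942-01-01", "female", "black", "2015-01-01"),  # 73
    mk("a3", "1960-01-01", "female", "white", "2015-01-01"),  # 55
    mk("a4", "1950-01-01", "male", "asian", "2015-01-01")))   # 65
}

test_that("cohort summaries tabulate matched patients exactly", {
  store <- demo_store()
  res <- execute_query('ICD9="233.0"', store)
  s <- summarize_cohort(res, store, k = 5L)
  expect_identical(s$n_patients, 4L)
  expect_identical(sum(s$age_histogram), 4L)
  expect_identical(unname(s$age_histogram[["70-79"]]), 2L)
  expect_identical(unname(s$age_histogram[["50-59"]]), 1L)
  expect_identical(unname(s$age_histogram[["60-69"]]), 1L)
  expect_identical(sum(s$record_length_histogram), 4L)
  expect_identical(as.integer(s$gender_counts[["female"]]), 3L)
  expect_identical(s$top_features$ICD$code, "ICD9:233.0")
  expect_identical(s$top_features$ICD$n_patients, 4L)
})

test_that("an empty result summarizes to zeros", {
  store <- demo_store()
  res <- execute_query('ICD9="999.9"', store)
  s <- summarize_cohort(res, store)
  expect_identical(s$n_patients, 0L)
  expect_identical(sum(s$age_histogram), 0L)
})

test_that("top features rank by distinct-patient count with lexicographic ties", {
  mk <- function(id, codes) {
    new_patient(id, 0L, "f", "w", c(0L, 1000L),
                events_frame(codes, seq(10L, by = 20L,
                                        length.out = length(codes))))
  }
  store <- build_store(list(
    mk("b1", c("ICD9:111", "ICD9:222")), mk("b2", "ICD9:111"),
    mk("b3", c("ICD9:111", "ICD9:333")), mk("b4", c("ICD9:222", "ICD9:333"))))
  res <- execute_query('OR(ICD9="111", ICD9="222", ICD9="333")', store)
  s <- summarize_cohort(res, store, k = 3L)
  expect_identical(s$top_features$ICD$code,
                   c("ICD9:111", "ICD9:222", "ICD9:333"))
  expect_identical(s$top_features$ICD$n_patients, c(3L, 2L, 2L))
})

test_that("timeline tracks reproduce per-variable evaluations", {
  dir <- withr::local_tempdir()
  generate_cohort(cohort_spec("diabetes_stroke", 60L, seed = 19L), dir)
  store <- load_omop(dir, onts[c("ICD9", "ICD10")], onts$drug_map)
  prog <- parse_tql(tql_example("diabetes_stroke"))
  res <- execute_query(prog, store)
  expect_gt(length(res$matches), 0L)
  tl <- cohort_timelines(res, store,
                         c("diabetes_then_glipizide", "glipizide_then_stroke"))
  expect_setequal(unique(tl$patient_id), matched_ids(res))
  for (i in seq_len(nrow(tl))) {
    p <- store$patients[[tl$patient_id[i]]]
    v <- evaluate_patient(list(op = "varref", name = tl$variable[i]), p,
                          prog$vars)
    expect_true(any(v[, 1L] == tl$start[i] & v[, 2L] == tl$end[i]))
  }
  expect_error(cohort_timelines(res, store, "no_such_var"), "unknown variable")
  tl0 <- cohort_timelines(res, store, character(0))
  expect_identical(nrow(tl0), 0L)
})

test_that("flat export emits one labeled row per matched patient", {
  dir <- withr::local_tempdir()
  generate_cohort(cohort_spec("t2d_labels", 80L, seed = 23L), dir)
  store <- load_omop(dir, onts[c("ICD9", "ICD10")], onts$drug_map)
  prog <- parse_tql(tql_example("t2d_labels"))
  res <- execute_query(prog, store)
  out_csv <- file.path(dir, "export.csv")
  df <- export_flat(prog, store, path = out_csv)
  expect_identical(nrow(df), length(res$matches))
  expect_identical(df$patient_id, matched_ids(res))
  expect_true(all(df$T2D == 1L))
  expect_identical(df$TIME, format(day_to_date(first_satisfaction(res)$first_day)))
  expect_identical(nrow(utils::read.csv(out_csv)), nrow(df))
})

test_that("export supports lab-valued columns and empty cohorts", {
  p <- new_patient("c1", 0L, "f", "w", c(0L, 1000L),
                   rbind(events_frame("ICD9:250.00", c(100L, 200L)),
                         events_frame("LOINC:4548-4 [%]", c(150L, 300L),
                                      value = c(9.5, 8.2))))
  store <- build_store(list(p))
  df <- export_flat('vart2d= COUNT(ICD9="250.00", 2, MAX)
EXPORT($t2d, TIME=$t2d, "T2D"=$t2d, "A1C"=LABS("4548-4 [%]", 8, MAX))', store)
  expect_identical(df$A1C, 9.5)  # earliest in-range value
  expect_identical(df$TIME, format(day_to_date(100L)))
  df0 <- export_flat('EXPORT(ICD9="999", TIME=ICD9="999", "Y"=ICD9="999")', store)
  expect_identical(nrow(df0), 0L)
  expect_identical(names(df0), c("patient_id", "TIME", "Y"))
  expect_error(export_flat('ICD9="1"', store), "must be EXPORT")
})

test_that("JSON results round-trip", {
  store <- demo_store()
  res <- execute_query('ICD9="233.0"', store)
  js <- result_to_json(res)
  back <- result_from_json(js)
  expect_identical(back, lapply(res$matches, function(m) {
    dimnames(m) <- list(NULL, c("start", "end")); m
  }))
  f <- withr::local_tempfile(fileext = ".json")
  result_to_json(res, path = f)
  expect_identical(result_from_json(f), back)
})

test_that("the CLI wires etl, query and synth together", {
  dir <- withr::local_tempdir()
  expect_identical(cli_main(character(0)), 2L)
  expect_identical(cli_main(c("query", "--data", dir)), 2L)

  suppressMessages(
    expect_identical(cli_main(c("synth", "--spec", "breast_ca_trial",
                                "--n", "50", "--seed", "31",
                                "--out", file.path(dir, "omop"))), 0L))
  suppressMessages(
    expect_identical(cli_main(c("etl", "--omop", file.path(dir, "omop"),
                                "--out", file.path(dir, "store"),
                                "--shards", "2")), 0L))
  qfile <- file.path(dir, "q.tql")
  writeLines(tql_example("breast_ca_trial"), qfile)
  out <- file.path(dir, "res.json")
  expect_identical(cli_main(c("query", "--data", file.path(dir, "store"),
                              "--query", qfile, "--out", out)), 0L)
  got <- result_from_json(out)
  # shard-store query equals in-memory load-and-execute
  store <- load_omop(file.path(dir, "omop"), onts[c("ICD9", "ICD10")],
                     onts$drug_map)
  want <- execute_query(tql_example("breast_ca_trial"), store)$matches
  expect_identical(names(got), names(want))
  expect_identical(lapply(got, unname), lapply(want, unname))

  # malformed TQL maps to exit 3 with a message naming the construct
  writeLines('SEQUENCE(ICD9="1", ICD9="2")', qfile)
  expect_message(
    st <- cli_main(c("query", "--data", file.path(dir, "store"),
                     "--query", qfile, "--out", out)),
    "starred")
  expect_identical(st, 3L)
  # missing data maps to exit 4
  expect_message(
    st <- cli_main(c("etl", "--omop", file.path(dir, "nope"),
                     "--out", file.path(dir, "s2"))), "no such directory")
  expect_identical(st, 4L)
})
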