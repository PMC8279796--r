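test_that("tokenizer splits juxtaposed var keywords, strings, refs and windows", {
  toks <- tokenize_tql('varstroke= ICD9="434.91"')
  expect_identical(toks$type, c("ident", "punct", "ident", "punct", "str"))
  expect_identical(toks$text, c("varstroke", "=", "ICD9", "=", "434.91"))
  expect_identical(nrow(tokenize_tql("")), 0L)
  toks <- tokenize_tql("+(-3 MONTHS, 0)")
  expect_identical(toks$type,
                   c("punct", "punct", "punct", "num", "ident", "punct", "num", "punct"))
  expect_identical(toks$text[5L], "MONTHS")
  # typographic quotes and minus normalize
  expect_identical(tokenize_tql("ICD9=“434.91”")$text[3L], "434.91")
  # comments are dropped; refs get their own type
  toks <- tokenize_tql("# note\n$stroke")
  expect_identical(toks$type, "ref")
  expect_identical(toks$text, "stroke")
})

test_that("tokenizer reports lexical errors with location", {
  expect_error(tokenize_tql('ICD9="unterminated'), "unterminated string")
  err <- tryCatch(tokenize_tql("UNION(a; b)"), tql_parse_error = identity)
  expect_match(conditionMessage(err), "illegal character ';'")
  expect_match(conditionMessage(err), "line 1")
})

test_that("a bare selector parses as a program with no variables", {
  p <- parse_tql('ICD9="434.91"')
  expect_length(p$vars, 0L)
  expect_identical(p$final, list(op = "selector", ns = "ICD9", code = "434.91"))
})

test_that("the diabetes-stroke program parses to the documented structure", {
  p <- parse_tql(tql_example("diabetes_stroke"))
  expect_identical(names(p$vars),
                   c("stroke", "male_patients_over_65", "glipizide",
                     "no_history_of_stroke", "diabetes", "diabetes_no_hx_stroke",
                     "diabetes_then_glipizide", "glipizide_then_stroke"))
  expect_identical(p$final$op, "intersect")
  expect_identical(vapply(p$final$args, `[[`, character(1L), "name"),
                   c("male_patients_over_65", "glipizide_then_stroke"))
  # the final sequence carries a presence window of (-90, 0] days
  sq <- p$vars$glipizide_then_stroke
  expect_identical(sq$op, "sequence")
  expect_identical(sq$star, "second")
  expect_identical(sq$window$mode, "presence")
  expect_identical(sq$window$lo, -90)
  expect_identical(sq$window$hi, 0)
  # AGE(65 YEARS, MAX) converts at 365 days/year with a MAX sentinel
  age <- p$vars$male_patients_over_65$args[[2L]]
  expect_identical(age, list(op = "age", lo = 65 * 365, hi = Inf))
})

test_that("absence windows parse from the minus prefix", {
  p <- parse_tql('varccvs= ICD9="491"
varbronchitis_cohort= ICD9="466.0"
SEQUENCE($ccvs,$bronchitis_cohort*)-(-1 YEAR, 1 DAY)')
  sq <- p$final
  expect_identical(sq$star, "second")
  expect_identical(sq$window$mode, "absence")
  expect_identical(sq$window$lo, -365)
  expect_identical(sq$window$hi, 1)
})

test_that("export programs parse cohort, TIME and labeled columns", {
  p <- parse_tql(tql_example("t2d_labels"))
  expect_identical(p$final$op, "export")
  expect_identical(p$final$cohort$name, "t2d_no_t1d")
  expect_identical(p$final$time$name, "t2d_no_t1d")
  expect_identical(names(p$final$labels), "T2D")
})

test_that("parse errors name the offending construct", {
  expect_error(parse_tql("INTERSECT($nope, $nope)"), "undefined variable")
  expect_error(parse_tql('varx= ICD9="1"
varx= ICD9="2"
$x'), "duplicate variable")
  expect_error(parse_tql('varx= ICD9="1"'), "no final query")
  expect_error(parse_tql('SEQUENCE(ICD9="1", ICD9="2")'), "starred")
  expect_error(parse_tql('SEQUENCE(ICD9="1"*, ICD9="2"*)'), "starred")
  expect_error(parse_tql('FROBNICATE(ICD9="1")'), "unknown command")
  expect_error(parse_tql('DIFF(ICD9="1")'), "exactly 2")
})

test_that("validation flags inverted bounds, nested EXPORT and bad ORIGINAL", {
  for (nm in c("diabetes_stroke", "bronchitis_hedis", "breast_ca_trial",
               "t2d_labels")) {
    expect_identical(validate_program(parse_tql(tql_example(nm))),
                     character(0))
  }
  expect_match(validate_program(parse_tql('COUNT(ICD9="1", 5, 2)')), "COUNT")
  p <- parse_tql('INTERSECT(EXPORT(ICD9="1", TIME=ICD9="1"), ICD9="2")')
  expect_match(validate_program(p), "top-level", all = FALSE)
  expect_match(validate_program(parse_tql('ORIGINAL(UNION(ICD9="1"))')),
               "ORIGINAL")
  expect_match(validate_program(parse_tql('EXPORT(ICD9="1")')), "TIME")
})

test_that("pretty-printed programs reparse to identical ASTs", {
  for (nm in c("diabetes_stroke", "bronchitis_hedis", "breast_ca_trial",
               "t2d_labels")) {
    p <- parse_tql(tql_example(nm))
    expect_identical(parse_tql(format_tql(p)), p, label = nm)
  }
})
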