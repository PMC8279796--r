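# Synthetic cohorts with planted ground truth ----------------------------
#
# Emits OMOP-subset CSV fixtures whose temporal structure is planted, so
# that each canonical example query has an exactly computable expected
# answer.  Four default specs correspond to the four example queries
# (diabetes_stroke, bronchitis_hedis, breast_ca_trial, t2d_labels).  Every
# patient draws from its own seeded random stream (derived from the spec
# seed and the patient index), so output is byte-identical for identical
# seeds and adding patients does not perturb existing ones.
#
# Background noise events use code pools disjoint from every code the
# example queries mention (and whose ontology ancestors are also disjoint
# from them), so noise can never create a false positive; the ground-truth
# table is computed analytically from each patient's full event list.

BG_ICD9 <- c("401.9", "272.4", "780.79", "715.90", "530.81")
BG_RX <- c("617314", "29046", "5640")
BG_CPT <- c("99213", "99214", "71020", "80053")
BG_LOINC <- "2160-0"
HBA1C <- "4548-4 [%]"

DEMO_RACES <- c("white", "black", "asian", "hispanic", "other")
DEMO_RACE_P <- c(0.5, 0.15, 0.15, 0.15, 0.05)

#' Synthetic cohort specification
#'
#' @param name One of `"diabetes_stroke"`, `"bronchitis_hedis"`,
#'   `"breast_ca_trial"`, `"t2d_labels"`.
#' @param n_patients Number of patients to simulate.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(name, n_patients = 400L, seed = 20260401L) {
  stopifnot(n_patients >= 0L, seed >= 0L)
  name <- match.arg(name, c("diabetes_stroke", "bronchitis_hedis",
                            "breast_ca_trial", "t2d_labels"))
  structure(list(name = name, n_patients = as.integer(n_patients),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Catalog of default cohort specs
#'
#' One spec per canonical example query, at the default sizes used by the
#' validation suite.
#'
#' @param seed Master seed applied to every spec.
#' @return Named list of `cohort_spec` objects.
#' @export
default_specs <- function(seed = 20260401L) {
  list(diabetes_stroke = cohort_spec("diabetes_stroke", 400L, seed),
       bronchitis_hedis = cohort_spec("bronchitis_hedis", 400L, seed),
       breast_ca_trial = cohort_spec("breast_ca_trial", 300L, seed),
       t2d_labels = cohort_spec("t2d_labels", 300L, seed))
}

patient_stream_seed <- function(spec, i) {
  h <- str_hash(spec$name) %% 977
  as.integer(((spec$seed %% 100000) * 20011 + h * 1009 + i * 7) %% 2147483647)
}

runs_of_days <- function(days) {
  days <- sort(unique(as.integer(days)))
  if (!length(days)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  brk <- c(TRUE, diff(days) > 1L)
  g <- cumsum(brk)
  data.frame(start = days[brk],
             end = as.integer(tapply(days, g, max)) + 1L)
}

ev_row <- function(ns, code, day, value = NA_real_, negated = FALSE,
                   family_history = FALSE, note_type = NA_character_) {
  n <- length(code)
  data.frame(ns = rep_len(ns, n), code = as.character(code),
             day = as.integer(day), value = rep_len(value, n),
             negated = rep_len(negated, n),
             family_history = rep_len(family_history, n),
             note_type = rep_len(note_type, n), stringsAsFactors = FALSE)
}

rand_day <- function(lo, hi, n = 1L) as.integer(floor(runif(n, lo, hi + 1)))

background_rows <- function(span, with_text = FALSE) {
  lo <- span[1L]; hi <- span[2L] - 1L
  out <- list()
  n_dx <- stats::rpois(1L, 2)
  if (n_dx > 0L) {
    out[[length(out) + 1L]] <- ev_row("ICD9", sample(BG_ICD9, n_dx, replace = TRUE),
                                      rand_day(lo, hi, n_dx))
  }
  n_rx <- stats::rpois(1L, 1)
  if (n_rx > 0L) {
    out[[length(out) + 1L]] <- ev_row("RX", sample(BG_RX, n_rx, replace = TRUE),
                                      rand_day(lo, hi, n_rx))
  }
  n_px <- stats::rpois(1L, 1)
  if (n_px > 0L) {
    out[[length(out) + 1L]] <- ev_row("CPT", sample(BG_CPT, n_px, replace = TRUE),
                                      rand_day(lo, hi, n_px))
  }
  n_lab <- stats::rpois(1L, 1)
  if (n_lab > 0L) {
    out[[length(out) + 1L]] <- ev_row("LOINC", rep(BG_LOINC, n_lab),
                                      rand_day(lo, hi, n_lab),
                                      value = round(runif(n_lab, 0.5, 1.5), 2))
  }
  if (with_text && runif(1) < 0.3) {
    out[[length(out) + 1L]] <- ev_row("TEXT", sample(c("cough", "fever"), 1L),
                                      rand_day(lo, hi), negated = runif(1) < 0.2,
                                      note_type = "progress note")
  }
  if (length(out)) do.call(rbind, out) else ev_row("ICD9", character(0), integer(0))
}

base_demographics <- function(birth_year_range) {
  by <- sample(seq(birth_year_range[1L], birth_year_range[2L]), 1L)
  birth <- date_to_day(sprintf("%04d-%02d-%02d", by, sample(1:12, 1L),
                               sample(1:28, 1L)))
  span_start <- date_to_day(sprintf("%04d-01-01", sample(2008:2011, 1L))) +
    sample(0:200, 1L)
  span_len <- sample((6 * 365):(10 * 365), 1L)
  list(birth = birth,
       gender = sample(c("male", "female"), 1L),
       race = sample(DEMO_RACES, 1L, prob = DEMO_RACE_P),
       span = c(span_start, span_start + span_len))
}

# per-event expanded code sets (ICD hierarchies only; used by truth rules)
expanded_codes <- function(rows, onts) {
  lapply(seq_len(nrow(rows)), function(i) {
    ont <- onts[[rows$ns[i]]]
    if (is.null(ont)) rows$code[i] else c(rows$code[i], ancestors(ont, rows$code[i]))
  })
}

days_matching_any <- function(rows, exp, ns, codes) {
  if (!nrow(rows)) return(integer(0))
  hit <- rows$ns == ns &
    vapply(exp, function(cs) any(cs %in% codes), logical(1L))
  sort(unique(rows$day[hit]))
}

exact_days <- function(rows, ns, code) {
  sort(unique(rows$day[rows$ns == ns & rows$code == code]))
}

hba1c_high_days <- function(rows) {
  sort(unique(rows$day[rows$ns == "LOINC" & rows$code == HBA1C &
                         !is.na(rows$value) & rows$value >= 8]))
}

# T2D onset day: FIRST MENTION of the union of the count-filtered code and
# lab day sets; NA when neither stream has >= 2 disjoint occurrences.
t2d_onset_day <- function(rows) {
  dx <- exact_days(rows, "ICD9", "250.00")
  if (nrow(runs_of_days(dx)) < 2L) dx <- integer(0)
  lab <- hba1c_high_days(rows)
  if (nrow(runs_of_days(lab)) < 2L) lab <- integer(0)
  q <- sort(unique(c(dx, lab)))
  if (!length(q)) NA_integer_ else q[1L]
}

# -- per-spec planting + analytic truth ----------------------------------

plant_diabetes_stroke <- function(i, demo) {
  span <- demo$span
  role <- if (i <= 3L) "exemplar" else {
    sample(c("trajectory", "early_stroke", "lab_path", "single_code",
             "no_glip", "background"), 1L,
           prob = c(0.28, 0.08, 0.10, 0.08, 0.06, 0.40))
  }
  rows <- list()
  if (role == "exemplar") {
    # guaranteed qualifying patient: old male, clean trajectory
    demo$gender <- "male"
    demo$birth <- date_to_day("1940-06-15")
    demo$span <- c(date_to_day("2008-01-01"), date_to_day("2018-01-01"))
    span <- demo$span
    d1 <- span[1L] + 400L + 50L * i
    rows[[1L]] <- ev_row("ICD9", c("250.00", "250.00"), c(d1, d1 + 60L))
    rows[[2L]] <- ev_row("RX", "310490", d1 + 120L)
    rows[[3L]] <- ev_row("ICD9", "434.91", d1 + 180L)
  } else if (role != "background") {
    d1 <- rand_day(span[1L] + 200L, span[2L] - 500L)
    gap <- sample(14:300, 1L)
    if (role == "lab_path") {
      rows[[1L]] <- ev_row("LOINC", rep(HBA1C, 2L), c(d1, d1 + gap),
                           value = round(runif(2L, 8, 12), 1))
    } else if (role == "single_code") {
      rows[[1L]] <- ev_row("ICD9", "250.00", d1)
    } else {
      rows[[1L]] <- ev_row("ICD9", c("250.00", "250.00"), c(d1, d1 + gap))
    }
    if (role != "no_glip") {
      gl <- d1 + sample(5:150, 1L)
      rows[[length(rows) + 1L]] <- ev_row("RX", "310490", gl)
      rows[[length(rows) + 1L]] <- ev_row("ICD9", "434.91", gl + sample(1:150, 1L))
    } else {
      rows[[length(rows) + 1L]] <- ev_row("ICD9", "434.91", d1 + sample(200:400, 1L))
    }
    if (role == "early_stroke") {
      rows[[length(rows) + 1L]] <- ev_row("ICD9", "434.91", d1 - sample(10:190, 1L))
    }
  }
  if (runif(1) < 0.3) {
    rows[[length(rows) + 1L]] <- ev_row("LOINC", HBA1C, rand_day(span[1L], span[2L] - 1L),
                                        value = round(runif(1, 5.5, 7.5), 1))
  }
  rows[[length(rows) + 1L]] <- background_rows(span, with_text = TRUE)
  list(demo = demo, rows = do.call(rbind, rows))
}

truth_diabetes_stroke <- function(demo, rows) {
  if (tolower(demo$gender) != "male") return(NA_integer_)
  span <- demo$span
  rows <- rows[rows$day >= span[1L] & rows$day < span[2L], , drop = FALSE]
  d0 <- t2d_onset_day(rows)
  if (is.na(d0)) return(NA_integer_)
  strokes <- exact_days(rows, "ICD9", "434.91")
  cutoff <- if (length(strokes)) min(strokes) else span[2L]
  if (d0 >= cutoff) return(NA_integer_)  # stroke before (or at) diabetes onset
  glip <- exact_days(rows, "RX", "310490")
  glip <- glip[glip > d0]
  if (!length(glip)) return(NA_integer_)
  ok <- strokes[vapply(strokes, function(s) any(glip >= s - 90L & glip <= s),
                       logical(1L))]
  age_lo <- demo$birth + 65L * 365L
  ok <- ok[ok >= age_lo]
  if (!length(ok)) NA_integer_ else min(ok)
}

HEDIS_CCVS <- c("279", "491", "494", "495", "500", "506", "507", "508",
                "510", "511", "512", "513", "516", "517", "518", "519",
                "010", "011", "012", "013", "014", "015", "016", "017", "018")
HEDIS_CDVS <- c("001", "002", "003", "004", "005", "006", "007", "008", "009",
                "033", "041.9", "088", "382", "461", "462", "034.0", "473",
                "464.1", "464.2", "464.3", "474", "478.21", "478.24", "478.29",
                "478.71", "478.79", "478.9", "601", "383", "681", "682", "730",
                "686", "482", "483", "484", "486", "098", "099", "V01.6",
                "090", "091", "092", "093", "094", "095", "096", "097",
                "078.88", "079.88")
HEDIS_MAL_NEO <- sprintf("%03d", c(140:165, 170:174, 176, 180, 182:184,
                                   186:192, 194:209))
HEDIS_ANTIBIOTIC <- c("641", "142438", "10109", "10627", "723", "733", "8339",
                      "10591", "2177", "2180", "2231", "20481", "274786",
                      "2582", "18631", "21212", "4053", "1272", "2348",
                      "229369", "22299", "190376", "6922", "11124", "7980",
                      "7984", "3356", "7233", "7773", "9384", "2176", "2187",
                      "19552", "2189", "2194", "10171", "10180", "3640",
                      "6980", "10395", "25037", "83682", "25033", "2186",
                      "20489", "2191", "20492", "2193", "4550", "7454", "10829")

# exclusion classes: code list + window (days relative to the bronchitis day)
hedis_classes <- function() {
  list(ccvs = list(codes = HEDIS_CCVS, ns = "ICD9", win = c(-365L, 1L)),
       cdvs = list(codes = HEDIS_CDVS, ns = "ICD9", win = c(-30L, 8L)),
       emphysema = list(codes = "492", ns = "ICD9", win = c(-365L, 1L)),
       copd = list(codes = c("493.2", "496"), ns = "ICD9", win = c(-365L, 1L)),
       cf = list(codes = "277.0", ns = "ICD9", win = c(-365L, 1L)),
       hiv = list(codes = "042", ns = "ICD9", win = c(-365L, 1L)),
       mal_neo = list(codes = HEDIS_MAL_NEO, ns = "ICD9", win = c(-365L, 1L)),
       antibiotic = list(codes = HEDIS_ANTIBIOTIC, ns = "RX", win = c(-30L, -1L)))
}

PLANT_CLASS_CODES <- c(ccvs = "491.21", cdvs = "482.9", emphysema = "492.8",
                       copd = "493.21", cf = "277.00", hiv = "042",
                       mal_neo = "153.9")

plant_bronchitis <- function(i, demo) {
  span <- demo$span
  role <- if (i <= 2L) "exemplar" else {
    sample(c("clean", "treated", "excluded_class", "class_outside",
             "prior_antibiotic", "age_out", "background"), 1L,
           prob = c(0.30, 0.15, 0.15, 0.08, 0.07, 0.05, 0.20))
  }
  rows <- list()
  if (role == "exemplar") {
    demo$birth <- date_to_day("1980-03-01")
    demo$span <- c(date_to_day("2009-01-01"), date_to_day("2017-01-01"))
    span <- demo$span
    b <- span[1L] + 700L + 31L * i
    rows[[1L]] <- ev_row("ICD9", "466.0", b)
    rows[[2L]] <- ev_row("RX", "723", b + 20L)  # antibiotic, outside all windows
  } else if (role != "background") {
    if (role == "age_out") {
      demo$birth <- date_to_day(sprintf("%04d-06-01",
                                        sample(c(1935:1944, 1996:2002), 1L)))
    }
    b <- rand_day(span[1L] + 800L, span[2L] - 100L)
    rows[[1L]] <- ev_row("ICD9", "466.0", b)
    if (role == "treated") {
      rows[[2L]] <- ev_row("RX", sample(HEDIS_ANTIBIOTIC, 1L), b + sample(0:3, 1L))
    } else if (role == "clean" && runif(1) < 0.5) {
      rows[[2L]] <- ev_row("RX", sample(HEDIS_ANTIBIOTIC, 1L), b + sample(9:40, 1L))
    } else if (role == "excluded_class") {
      cls <- sample(names(PLANT_CLASS_CODES), 1L)
      off <- if (cls == "cdvs") sample(-25:5, 1L) else sample(-300:0, 1L)
      rows[[2L]] <- ev_row("ICD9", PLANT_CLASS_CODES[[cls]], b + off)
    } else if (role == "class_outside") {
      cls <- sample(names(PLANT_CLASS_CODES), 1L)
      rows[[2L]] <- ev_row("ICD9", PLANT_CLASS_CODES[[cls]], b - sample(400:700, 1L))
    } else if (role == "prior_antibiotic") {
      rows[[2L]] <- ev_row("RX", sample(HEDIS_ANTIBIOTIC, 1L), b - sample(1:30, 1L))
    }
  }
  rows[[length(rows) + 1L]] <- background_rows(span)
  list(demo = demo, rows = do.call(rbind, rows))
}

truth_bronchitis <- function(demo, rows, onts) {
  span <- demo$span
  rows <- rows[rows$day >= span[1L] & rows$day < span[2L], , drop = FALSE]
  if (!nrow(rows)) return(NA_integer_)
  exp <- expanded_codes(rows, onts)
  age_lo <- demo$birth + 18L * 365L
  age_hi <- demo$birth + 64L * 365L
  b_days <- exact_days(rows, "ICD9", "466.0")
  b_days <- b_days[b_days >= age_lo & b_days < age_hi]
  if (!length(b_days)) return(NA_integer_)
  classes <- hedis_classes()
  class_days <- lapply(classes, function(cl) {
    if (cl$ns == "RX") {
      sort(unique(rows$day[rows$ns == "RX" & rows$code %in% cl$codes]))
    } else {
      days_matching_any(rows, exp, cl$ns, cl$codes)
    }
  })
  denom <- b_days[vapply(b_days, function(b) {
    all(mapply(function(cl, cd) !any(cd >= b + cl$win[1L] & cd <= b + cl$win[2L]),
               classes, class_days))
  }, logical(1L))]
  if (!length(denom)) return(NA_integer_)
  abx <- class_days$antibiotic
  treated <- any(vapply(abx, function(a) any(denom >= a - 3L & denom <= a),
                        logical(1L)))
  if (treated) NA_integer_ else min(denom)
}

plant_breast_ca <- function(i, demo) {
  span <- demo$span
  role <- if (i <= 2L) "exemplar" else {
    sample(c("eligible", "prior_ca", "young", "male_cis", "later_ca",
             "background"), 1L, prob = c(0.25, 0.12, 0.10, 0.08, 0.07, 0.38))
  }
  rows <- list()
  if (role == "exemplar") {
    demo$gender <- "female"
    demo$birth <- date_to_day("1935-05-20")
    demo$span <- c(date_to_day("2008-01-01"), date_to_day("2017-01-01"))
    span <- demo$span
    rows[[1L]] <- ev_row("ICD9", "233.0", span[1L] + 500L + 40L * i)
  } else if (role != "background") {
    if (role == "young") {
      demo$birth <- date_to_day(sprintf("%04d-06-01", sample(1950:1970, 1L)))
    } else {
      demo$birth <- date_to_day(sprintf("%04d-06-01", sample(1925:1942, 1L)))
    }
    demo$gender <- if (role == "male_cis") "male" else "female"
    d <- rand_day(span[1L] + 600L, span[2L] - 50L)
    rows[[1L]] <- ev_row("ICD9", "233.0", d)
    if (role == "prior_ca") {
      code <- sample(c("174", "174.9"), 1L)  # 174.9 matches 174 via expansion
      rows[[2L]] <- ev_row("ICD9", code, d - sample(30:500, 1L))
    } else if (role == "later_ca") {
      rows[[2L]] <- ev_row("ICD9", "174", d + sample(10:300, 1L))
    }
  }
  rows[[length(rows) + 1L]] <- background_rows(span)
  list(demo = demo, rows = do.call(rbind, rows))
}

truth_breast_ca <- function(demo, rows, onts) {
  if (tolower(demo$gender) != "female") return(NA_integer_)
  span <- demo$span
  rows <- rows[rows$day >= span[1L] & rows$day < span[2L], , drop = FALSE]
  if (!nrow(rows)) return(NA_integer_)
  exp <- expanded_codes(rows, onts)
  cis <- exact_days(rows, "ICD9", "233.0")
  prior <- days_matching_any(rows, exp, "ICD9", "174")
  cutoff <- if (length(prior)) min(prior) else span[2L]
  ok <- cis[cis < cutoff & cis >= demo$birth + 70L * 365L]
  if (!length(ok)) NA_integer_ else min(ok)
}

plant_t2d_labels <- function(i, demo) {
  span <- demo$span
  role <- if (i <= 2L) "exemplar" else {
    sample(c("codes", "labs", "confounded", "single_code", "low_labs",
             "background"), 1L, prob = c(0.25, 0.10, 0.12, 0.08, 0.05, 0.40))
  }
  rows <- list()
  if (role == "exemplar") {
    demo$span <- c(date_to_day("2009-01-01"), date_to_day("2018-01-01"))
    span <- demo$span
    d1 <- span[1L] + 300L + 45L * i
    rows[[1L]] <- ev_row("ICD9", c("250.00", "250.00"), c(d1, d1 + 90L))
  } else if (role != "background") {
    d1 <- rand_day(span[1L] + 100L, span[2L] - 400L)
    gap <- sample(14:300, 1L)
    if (role == "labs") {
      rows[[1L]] <- ev_row("LOINC", rep(HBA1C, 2L), c(d1, d1 + gap),
                           value = round(runif(2L, 8, 12), 1))
    } else if (role == "low_labs") {
      rows[[1L]] <- ev_row("LOINC", rep(HBA1C, 2L), c(d1, d1 + gap),
                           value = round(runif(2L, 5.5, 7.9), 1))
    } else if (role == "single_code") {
      rows[[1L]] <- ev_row("ICD9", "250.00", d1)
    } else {
      rows[[1L]] <- ev_row("ICD9", c("250.00", "250.00"), c(d1, d1 + gap))
    }
    if (role == "confounded") {
      rows[[2L]] <- ev_row("ICD9", sample(c("250.01", "250.03"), 1L),
                           rand_day(span[1L], span[2L] - 1L))
    }
  }
  rows[[length(rows) + 1L]] <- background_rows(span)
  list(demo = demo, rows = do.call(rbind, rows))
}

truth_t2d_labels <- function(demo, rows) {
  span <- demo$span
  rows <- rows[rows$day >= span[1L] & rows$day < span[2L], , drop = FALSE]
  if (!nrow(rows)) return(NA_integer_)
  t1d <- rows$ns == "ICD9" & rows$code %in% c("250.01", "250.03")
  if (any(t1d)) return(NA_integer_)
  t2d_onset_day(rows)
}

BIRTH_YEAR_RANGE <- list(diabetes_stroke = c(1930, 1975),
                         bronchitis_hedis = c(1950, 1995),
                         breast_ca_trial = c(1925, 1970),
                         t2d_labels = c(1940, 1985))

#' Simulate a synthetic cohort in memory
#'
#' @param spec A `cohort_spec`.
#' @param ontologies Ontology list (see [default_ontologies()]) used both
#'   for the analytic ground-truth rules and, downstream, for load-time
#'   expansion.
#' @return A list with `person` (demographics), `events` (long event
#'   table), and `truth` (patient id + first satisfaction day for the
#'   spec's canonical query).
#' @export
simulate_cohort <- function(spec, ontologies = default_ontologies()) {
  onts <- list(ICD9 = ontologies$ICD9, ICD10 = ontologies$ICD10)
  persons <- list()
  events <- list()
  truth <- list()
  n <- spec$n_patients
  for (i in seq_len(n)) {
    set.seed(patient_stream_seed(spec, i))
    demo <- base_demographics(BIRTH_YEAR_RANGE[[spec$name]])
    planted <- switch(spec$name,
      diabetes_stroke = plant_diabetes_stroke(i, demo),
      bronchitis_hedis = plant_bronchitis(i, demo),
      breast_ca_trial = plant_breast_ca(i, demo),
      t2d_labels = plant_t2d_labels(i, demo))
    demo <- planted$demo
    rows <- planted$rows
    pid <- sprintf("P%05d", i)
    first_day <- switch(spec$name,
      diabetes_stroke = truth_diabetes_stroke(demo, rows),
      bronchitis_hedis = truth_bronchitis(demo, rows, onts),
      breast_ca_trial = truth_breast_ca(demo, rows, onts),
      t2d_labels = truth_t2d_labels(demo, rows))
    persons[[i]] <- data.frame(person_id = pid, birth_day = demo$birth,
                               gender = demo$gender, race = demo$race,
                               span_start = demo$span[1L],
                               span_end = demo$span[2L],
                               stringsAsFactors = FALSE)
    if (nrow(rows)) {
      rows$person_id <- pid
      events[[length(events) + 1L]] <- rows
    }
    if (!is.na(first_day)) {
      truth[[length(truth) + 1L]] <- data.frame(patient_id = pid,
                                                first_day = first_day,
                                                stringsAsFactors = FALSE)
    }
  }
  person <- if (length(persons)) do.call(rbind, persons) else
    data.frame(person_id = character(0), birth_day = integer(0),
               gender = character(0), race = character(0),
               span_start = integer(0), span_end = integer(0))
  ev <- if (length(events)) do.call(rbind, events) else
    cbind(ev_row("ICD9", character(0), integer(0)), person_id = character(0))
  tr <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient_id = character(0), first_day = integer(0))
  tr <- tr[order(tr$patient_id), , drop = FALSE]
  rownames(tr) <- NULL
  list(person = person, events = ev, truth = tr, spec = spec)
}

#' Write a simulated cohort as an OMOP-subset CSV directory
#'
#' Emits `person.csv`, `observation_period.csv`, `condition_occurrence.csv`,
#' `procedure_occurrence.csv`, `drug_exposure.csv`, `measurement.csv`,
#' `text_mention.csv`, plus `ground_truth.csv` (patient id and first
#' satisfaction day/date of the spec's canonical query) and `spec.json`.
#' Identical spec and seed give byte-identical output.
#'
#' @param spec A `cohort_spec`.
#' @param out_dir Output directory (created if needed).
#' @param ontologies Ontology list used by the ground-truth rules.
#' @return Invisibly, the simulation list from [simulate_cohort()].
#' @export
generate_cohort <- function(spec, out_dir, ontologies = default_ontologies()) {
  sim <- simulate_cohort(spec, ontologies)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- sim$person
  ev <- sim$events
  by <- as.integer(format(day_to_date(p$birth_day), "%Y"))
  bm <- as.integer(format(day_to_date(p$birth_day), "%m"))
  bd <- as.integer(format(day_to_date(p$birth_day), "%d"))
  zero <- rep(0L, nrow(p))
  data.table::fwrite(data.frame(
    person_id = p$person_id, gender_concept_id = zero, year_of_birth = by,
    month_of_birth = bm, day_of_birth = bd, race_concept_id = zero,
    ethnicity_concept_id = zero, gender_source_value = p$gender,
    race_source_value = p$race), file.path(out_dir, "person.csv"))
  data.table::fwrite(data.frame(
    observation_period_id = seq_len(nrow(p)), person_id = p$person_id,
    observation_period_start_date = format(day_to_date(p$span_start)),
    observation_period_end_date = format(day_to_date(p$span_end - 1L)),
    period_type_concept_id = zero), file.path(out_dir, "observation_period.csv"))

  tab <- function(sel) ev[sel, , drop = FALSE]
  cond <- tab(ev$ns %in% c("ICD9", "ICD10"))
  data.table::fwrite(data.frame(
    condition_occurrence_id = seq_len(nrow(cond)), person_id = cond$person_id,
    condition_start_date = format(day_to_date(cond$day)),
    condition_source_value = sprintf("%s:%s", cond$ns, cond$code)),
    file.path(out_dir, "condition_occurrence.csv"))
  proc <- tab(ev$ns == "CPT")
  data.table::fwrite(data.frame(
    procedure_occurrence_id = seq_len(nrow(proc)), person_id = proc$person_id,
    procedure_date = format(day_to_date(proc$day)),
    procedure_source_value = proc$code),
    file.path(out_dir, "procedure_occurrence.csv"))
  drug <- tab(ev$ns == "RX")
  data.table::fwrite(data.frame(
    drug_exposure_id = seq_len(nrow(drug)), person_id = drug$person_id,
    drug_exposure_start_date = format(day_to_date(drug$day)),
    drug_exposure_end_date = format(day_to_date(drug$day)),
    drug_source_value = drug$code), file.path(out_dir, "drug_exposure.csv"))
  meas <- tab(ev$ns == "LOINC")
  data.table::fwrite(data.frame(
    measurement_id = seq_len(nrow(meas)), person_id = meas$person_id,
    measurement_date = format(day_to_date(meas$day)),
    measurement_source_value = meas$code, value_as_number = meas$value),
    file.path(out_dir, "measurement.csv"))
  txt <- tab(ev$ns == "TEXT")
  data.table::fwrite(data.frame(
    person_id = txt$person_id, note_date = format(day_to_date(txt$day)),
    phrase = txt$code, negated = as.integer(txt$negated),
    family_history = as.integer(txt$family_history),
    note_type = txt$note_type), file.path(out_dir, "text_mention.csv"))

  truth_out <- sim$truth
  truth_out$first_date <- format(day_to_date(truth_out$first_day))
  data.table::fwrite(truth_out, file.path(out_dir, "ground_truth.csv"))
  jsonlite::write_json(list(name = spec$name, n_patients = spec$n_patients,
                            seed = spec$seed, epoch = format(tql_epoch())),
                       file.path(out_dir, "spec.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(sim)
}

#' Read the ground-truth table of a generated cohort directory
#'
#' @param dir A directory written by [generate_cohort()].
#' @return Data frame with `patient_id`, `first_day`, `first_date`.
#' @export
read_ground_truth <- function(dir) {
  as.data.frame(data.table::fread(file.path(dir, "ground_truth.csv"),
                                  colClasses = list(character = "patient_id"),
                                  showProgress = FALSE))
}

#' Generate a randomized in-memory store for engine validation
#'
#' Builds patient objects directly (no CSV round trip) with random events
#' drawn from a fixed vocabulary across the ICD9/ICD10/CPT/RX namespaces,
#' the shape used by the randomized index-versus-scan and interpreter
#' equivalence suites.
#'
#' @param n_patients Number of patients.
#' @param seed Master seed.
#' @param events_per_patient Mean number of events per patient (Poisson).
#' @param vocab Optional character vector of feature keys to draw from.
#' @param expand Apply knowledge expansion with the fixture ontologies.
#' @return A `tql_store`.
#' @export
random_patient_store <- function(n_patients, seed = 1L,
                                 events_per_patient = 20,
                                 vocab = NULL, expand = FALSE) {
  if (is.null(vocab)) {
    vocab <- c(paste0("ICD9:", c("250.00", "250.02", "434.91", "466.0", "401.9",
                                 "272.4", "174", "233.0", "492", "042")),
               paste0("ICD10:", c("E11.9", "I63.9", "J20.9")),
               paste0("CPT:", BG_CPT),
               paste0("RX:", c("310490", "161", "723", BG_RX)),
               "LOINC:2160-0", "TEXT:fever")
  }
  onts <- if (expand) default_ontologies() else NULL
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(as.integer(((seed %% 100000) * 20011 + i * 13) %% 2147483647))
    span_start <- date_to_day("2010-01-01") + sample(0:365, 1L)
    span <- c(span_start, span_start + sample(1000:3000, 1L))
    birth <- date_to_day(sprintf("%04d-06-01", sample(1930:1990, 1L)))
    k <- stats::rpois(1L, events_per_patient)
    ev <- if (k > 0L) {
      keys <- sample(vocab, k, replace = TRUE)
      is_lab <- startsWith(keys, "LOINC:")
      is_text <- startsWith(keys, "TEXT:")
      events_frame(keys, rand_day(span[1L], span[2L] - 1L, k),
                   value = ifelse(is_lab, round(runif(k, 0, 2), 2), NA_real_),
                   negated = is_text & runif(k) < 0.2,
                   family_history = is_text & runif(k) < 0.1)
    } else empty_events()
    p <- new_patient(sprintf("R%05d", i), birth,
                     sample(c("male", "female"), 1L),
                     sample(DEMO_RACES, 1L), span, ev)
    if (expand) p <- expand_events(p, onts[c("ICD9", "ICD10")], onts$drug_map)
    patients[[i]] <- p
  }
  build_store(patients)
}
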