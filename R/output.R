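# Result surfaces --------------------------------------------------------
#
# A query result can be rendered as (1) cohort summary statistics (counts,
# age / record-length histograms, demographic tabulations, most frequent
# codes), (2) per-patient timeline tracks for selected variables, (3) a
# labeled flat-file export, or (4) JSON.

#' Summarize a matched cohort
#'
#' Statistics are computed over matched patients only.  Age is the age (in
#' fixed 365-day years) at the start of each patient's first matched
#' interval, binned in 10-year bins `0-9` .. `90-99` and `100+`; record
#' length is the observation-period length in whole years, one bin per
#' year.  `top_features` ranks codes per namespace by the number of
#' distinct matched patients with at least one *original* (non-derived)
#' event of the code, ties broken lexicographically.
#'
#' @param result A `tql_result`.
#' @param store The `tql_store` the query ran against.
#' @param k Number of top codes per namespace.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(result, store, k = 10L) {
  stopifnot(k >= 1L)
  ids <- matched_ids(result)
  n <- length(ids)
  age_breaks <- c(seq(0L, 100L, 10L), Inf)
  age_labels <- c(paste(seq(0L, 90L, 10L), seq(9L, 99L, 10L), sep = "-"), "100+")
  if (n == 0L) {
    age_hist <- setNames(integer(length(age_labels)), age_labels)
    return(structure(list(n_patients = 0L, age_histogram = age_hist,
                          record_length_histogram = integer(0),
                          gender_counts = integer(0), race_counts = integer(0),
                          top_features = list()),
                     class = "cohort_summary"))
  }
  pats <- store$patients[ids]
  first_day <- vapply(result$matches, function(m) m[1L, 1L], integer(1L))
  age_years <- (first_day - vapply(pats, `[[`, integer(1L), "birth_day")) %/% 365L
  age_bin <- cut(age_years, breaks = age_breaks, labels = age_labels,
                 right = FALSE)
  age_hist <- setNames(as.integer(table(age_bin)), age_labels)
  rec_years <- vapply(pats, function(p) (p$span[2L] - p$span[1L]) %/% 365L,
                      integer(1L))
  rec_hist <- table(factor(rec_years, levels = 0:max(rec_years)))
  gender_counts <- sort(table(vapply(pats, `[[`, character(1L), "gender")),
                        decreasing = TRUE)
  race_counts <- sort(table(vapply(pats, `[[`, character(1L), "race")),
                      decreasing = TRUE)

  ns_groups <- list(ICD = c("ICD9", "ICD10"), CPT = "CPT", RX = "RX",
                    LOINC = "LOINC")
  top_features <- lapply(ns_groups, function(nss) {
    per_patient <- lapply(pats, function(p) {
      ev <- p$events
      keys <- unique(ev$key[ev$original & sub(":.*$", "", ev$key) %in% nss])
      keys
    })
    tab <- table(unlist(per_patient, use.names = FALSE))
    if (!length(tab)) {
      return(data.frame(code = character(0), n_patients = integer(0)))
    }
    df <- data.frame(code = names(tab), n_patients = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n_patients, df$code), , drop = FALSE]
    rownames(df) <- NULL
    head(df, k)
  })
  structure(list(n_patients = n, age_histogram = age_hist,
                 record_length_histogram = setNames(as.integer(rec_hist),
                                                    names(rec_hist)),
                 gender_counts = gender_counts, race_counts = race_counts,
                 top_features = top_features),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort summary> %d patients\n", x$n_patients))
  if (x$n_patients > 0L) {
    cat("age (10-year bins):\n")
    print(x$age_histogram[x$age_histogram > 0L])
    cat("gender:\n"); print(x$gender_counts)
  }
  invisible(x)
}

#' Per-patient timeline tracks for named variables
#'
#' For each matched patient, re-evaluates the requested program variables
#' and returns their interval sets as long-format rows -- the data behind a
#' patient timeline display with one colored track per variable.
#'
#' @param result A `tql_result`.
#' @param store The store the query ran against.
#' @param vars Character vector of variable names defined in the program.
#' @return Data frame with `patient_id`, `variable`, `start`, `end`,
#'   `start_date`, `end_date`.
#' @export
cohort_timelines <- function(result, store, vars) {
  defs <- result$program$vars
  unknown <- setdiff(vars, names(defs))
  if (length(unknown)) {
    stop_eval(paste0("unknown variable(s): ", paste(unknown, collapse = ", ")))
  }
  out <- list()
  for (id in matched_ids(result)) {
    p <- store$patients[[id]]
    bindings <- new.env(parent = emptyenv())
    for (v in vars) {
      m <- evaluate_patient(list(op = "varref", name = v), p, defs, bindings)
      if (nrow(m)) {
        out[[length(out) + 1L]] <- data.frame(
          patient_id = id, variable = v, start = m[, 1L], end = m[, 2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(0), variable = character(0),
               start = integer(0), end = integer(0))
  df$start_date <- day_to_date(df$start)
  df$end_date <- day_to_date(df$end)
  rownames(df) <- NULL
  df
}

#' Export a cohort as a labeled flat table
#'
#' Executes a program whose final expression is EXPORT and builds one row
#' per matched patient: `patient_id`, `TIME` (ISO date of the start of the
#' first interval of the TIME expression), and one column per label --
#' a 1/0 non-empty indicator for interval-valued expressions, or the first
#' in-range value for a LABS expression.
#'
#' @param program A `tql_program` (or TQL text) with a top-level EXPORT.
#' @param store A `tql_store`.
#' @param path Optional CSV output path.
#' @return The export data frame (written to `path` when given).
#' @export
export_flat <- function(program, store, path = NULL) {
  if (is.character(program)) program <- parse_tql(program)
  if (program$final$op != "export") {
    stop_eval("program's final expression must be EXPORT")
  }
  res <- execute_query(program, store)
  ex <- program$final
  defs <- program$vars
  rows <- list()
  for (id in matched_ids(res)) {
    p <- store$patients[[id]]
    bindings <- new.env(parent = emptyenv())
    tm <- evaluate_patient(ex$time, p, defs, bindings)
    if (nrow(tm) == 0L) {
      stop_eval(paste0("patient ", id, ": TIME expression evaluates to empty"))
    }
    row <- list(patient_id = id, TIME = format(day_to_date(tm[1L, 1L])))
    for (nm in names(ex$labels)) {
      le <- ex$labels[[nm]]
      v <- evaluate_patient(le, p, defs, bindings)
      row[[nm]] <- if (le$op == "labs") {
        ev <- p$events
        sel <- ev$key == paste0("LOINC:", le$code) & !is.na(ev$value) &
          ev$value >= le$lo & ev$value <= le$hi
        if (any(sel)) ev$value[sel][order(ev$start[sel])][1L] else NA_real_
      } else {
        as.integer(nrow(v) > 0L)
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c(list(patient_id = character(0), TIME = character(0)),
              setNames(rep(list(integer(0)), length(names(ex$labels))),
                       names(ex$labels)))
    as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!is.null(path)) data.table::fwrite(df, path)
  df
}

#' Serialize a query result to JSON
#'
#' The schema is `{n_patients, n_candidates, matches: [{patient_id,
#' intervals: [{start, end}]}]}` with ISO-8601 dates (`end` is the
#' exclusive bound).
#'
#' @param result A `tql_result`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
result_to_json <- function(result, path = NULL) {
  matches <- lapply(matched_ids(result), function(id) {
    m <- result$matches[[id]]
    list(patient_id = id,
         intervals = lapply(seq_len(nrow(m)), function(i) {
           list(start = format(day_to_date(m[i, 1L])),
                end = format(day_to_date(m[i, 2L])))
         }))
  })
  obj <- list(n_patients = length(result$matches),
              n_candidates = result$n_candidates,
              matches = matches)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse a result JSON back to a matches list
#'
#' @param json JSON text or a file path produced by [result_to_json()].
#' @return Named list: patient id -> canonical interval-set matrix.
#' @export
result_from_json <- function(json) {
  txt <- if (length(json) == 1L && nchar(json) < 1000L && file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    paste(json, collapse = "\n")
  }
  obj <- jsonlite::parse_json(txt)
  out <- list()
  for (m in obj$matches) {
    ivs <- do.call(rbind, lapply(m$intervals, function(iv) {
      c(date_to_day(iv$start), date_to_day(iv$end))
    }))
    out[[m$patient_id]] <- iset_matrix(ivs[, 1L], ivs[, 2L])
  }
  out
}

#' Canonical example query programs
#'
#' Returns the text of the bundled example TQL programs: a
#' diabetes-then-stroke pharmacovigilance cohort (`diabetes_stroke`), an
#' antibiotics-avoidance HEDIS-style quality measure (`bronchitis_hedis`),
#' breast-carcinoma-in-situ trial inclusion criteria (`breast_ca_trial`),
#' and a labeled type-2-diabetes training-data export (`t2d_labels`).
#'
#' @param name Example name; see above.
#' @return TQL source text (single string).
#' @export
tql_example <- function(name = c("diabetes_stroke", "bronchitis_hedis",
                                 "breast_ca_trial", "t2d_labels")) {
  name <- match.arg(name)
  path <- system.file("extdata", "queries", paste0(name, ".tql"),
                      package = "cohortql")
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}
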