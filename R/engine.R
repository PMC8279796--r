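# Query execution --------------------------------------------------------
#
# Two-phase execution: (1) a structural pass over the AST combines inverted
# feature-index postings into a *sound* candidate set -- every patient that
# could possibly match is retained; (2) each candidate patient object is
# fully evaluated, recursively, to the interval set where the query is true
# for that patient.  Variables are evaluated lazily per patient, in
# definition order, and memoized within that patient's evaluation.

stop_eval <- function(msg) {
  stop(structure(class = c("tql_eval_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

span_iset <- function(p) iset_matrix(p$span[1L], p$span[2L])

eval_selector <- function(e, p, original_only) {
  if (e$ns %in% c("GENDER", "RACE")) {
    attr_val <- if (e$ns == "GENDER") p$gender else p$race
    return(if (tolower(attr_val) == tolower(e$code)) span_iset(p) else empty_iset())
  }
  key <- paste0(e$ns, ":", e$code)
  sets <- if (original_only) p$key_sets_orig else p$key_sets
  m <- sets[[key]]
  if (is.null(m)) empty_iset() else m
}

eval_labs <- function(e, p) {
  key <- paste0("LOINC:", e$code)
  ev <- p$events
  sel <- ev$key == key & !is.na(ev$value) & ev$value >= e$lo & ev$value <= e$hi
  if (!any(sel)) return(empty_iset())
  coalesce_intervals(ev$start[sel], ev$end[sel])
}

eval_text <- function(e, p) {
  key <- paste0("TEXT:", e$phrase)
  ev <- p$events
  sel <- ev$key == key
  sel <- sel & switch(e$flag,
                      plain = !ev$negated & !ev$family_history,
                      negated = ev$negated,
                      family_history = ev$family_history)
  if (!any(sel)) return(empty_iset())
  coalesce_intervals(ev$start[sel], ev$end[sel])
}

eval_age <- function(e, p) {
  lo <- p$birth_day + e$lo
  hi <- if (is.infinite(e$hi)) p$span[2L] else p$birth_day + e$hi
  iset_clip(iset_matrix(p$span[1L], p$span[2L]),
            as.integer(max(lo, p$span[1L])),
            as.integer(min(hi, p$span[2L])))
}

eval_year <- function(e, p) {
  lo <- date_to_day(sprintf("%04d-01-01", as.integer(e$lo)))
  hi <- date_to_day(sprintf("%04d-01-01", as.integer(e$hi) + 1L))
  iset_clip(span_iset(p), lo, hi)
}

bool_result <- function(p, truth) if (truth) span_iset(p) else empty_iset()

#' Evaluate a TQL expression for one patient
#'
#' The per-patient interpreter behind [execute_query()].  `bindings` is an
#' environment used to memoize variable values for this patient; it is
#' filled lazily from `defs` in definition order.
#'
#' @param expr An expression AST (a component of a parsed `tql_program`).
#' @param patient A `tql_patient`.
#' @param defs Named list of variable ASTs the expression may reference.
#' @param bindings Environment memoizing per-patient variable values.
#' @param original_only Evaluate feature selectors against original (not
#'   expansion-derived) events; set internally by ORIGINAL.
#' @return A canonical interval-set matrix.
#' @export
evaluate_patient <- function(expr, patient, defs = list(),
                             bindings = new.env(parent = emptyenv()),
                             original_only = FALSE) {
  ev <- function(e, orig = original_only) {
    switch(e$op,
      selector = eval_selector(e, patient, orig),
      labs = eval_labs(e, patient),
      text = eval_text(e, patient),
      age = eval_age(e, patient),
      year = eval_year(e, patient),
      varref = {
        if (!exists(e$name, envir = bindings, inherits = FALSE)) {
          d <- defs[[e$name]]
          if (is.null(d)) stop_eval(paste0("undefined variable $", e$name))
          assign(e$name, evaluate_patient(d, patient, defs, bindings), bindings)
        }
        get(e$name, envir = bindings, inherits = FALSE)
      },
      union = t_union(lapply(e$args, ev)),
      intersect = t_intersect(lapply(e$args, ev)),
      invert = t_invert(ev(e$arg), patient$span),
      sequence = t_sequence(ev(e$first), ev(e$second), e$star, e$window),
      count = t_count(ev(e$arg), e$min, e$max),
      first_mention = t_first_mention(ev(e$arg)),
      no_history_of = t_no_history_of(ev(e$arg), patient$span),
      never_had = t_never_had(ev(e$arg), patient$span),
      original = ev(e$arg, orig = TRUE),
      and = bool_result(patient, all(vapply(e$args, function(a) nrow(ev(a)) > 0L, logical(1L)))),
      or = bool_result(patient, any(vapply(e$args, function(a) nrow(ev(a)) > 0L, logical(1L)))),
      not = bool_result(patient, !any(vapply(e$args, function(a) nrow(ev(a)) > 0L, logical(1L)))),
      diff = {
        a <- ev(e$args[[1L]])
        if (nrow(ev(e$args[[2L]])) == 0L) a else empty_iset()
      },
      export = ev(e$cohort),
      stop_eval(paste0("cannot evaluate construct '", e$op, "'")))
  }
  ev(expr)
}

# sound candidate sets ---------------------------------------------------
# NULL means "all patients" (the sound fallback for negation-bearing
# constructs); character vectors are id sets.

cand_union <- function(a, b) if (is.null(a) || is.null(b)) NULL else union(a, b)
cand_intersect <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  intersect(a, b)
}

#' Candidate patient set for a query expression
#'
#' Combines inverted-index postings structurally into a sound
#' overapproximation of the match set: every patient whose full evaluation
#' is non-empty is guaranteed to be a candidate.  Negation-bearing
#' constructs (NOT, INVERT, NO HISTORY OF, NEVER HAD, the second operand of
#' DIFF, absence windows) contribute "all patients" for their branch.
#'
#' @param expr An expression AST.
#' @param store A `tql_store`.
#' @param defs Named list of variable ASTs.
#' @param memo Environment memoizing per-variable candidate sets.
#' @return Character vector of patient ids, or `NULL` meaning all patients.
#' @export
candidate_set <- function(expr, store, defs = list(),
                          memo = new.env(parent = emptyenv())) {
  cand <- function(e) {
    switch(e$op,
      selector = {
        if (e$ns %in% c("GENDER", "RACE")) {
          index_lookup(store, paste0(e$ns, ":", tolower(e$code)))
        } else {
          index_lookup(store, paste0(e$ns, ":", e$code))
        }
      },
      labs = index_lookup(store, paste0("LOINC:", e$code)),
      text = index_lookup(store, paste0("TEXT:", e$phrase)),
      age = NULL,
      year = NULL,
      varref = {
        if (!exists(e$name, envir = memo, inherits = FALSE)) {
          d <- defs[[e$name]]
          if (is.null(d)) stop_eval(paste0("undefined variable $", e$name))
          v <- cand(d)
          assign(e$name, if (is.null(v)) list(NULL) else v, memo)
        }
        v <- get(e$name, envir = memo, inherits = FALSE)
        if (is.list(v)) NULL else v
      },
      union = Reduce(cand_union, lapply(e$args, cand)),
      or = Reduce(cand_union, lapply(e$args, cand)),
      intersect = Reduce(cand_intersect, lapply(e$args, cand)),
      and = Reduce(cand_intersect, lapply(e$args, cand)),
      sequence = {
        starred <- if (e$star == "first") e$first else e$second
        other <- if (e$star == "first") e$second else e$first
        s <- cand(starred)
        if (!is.null(e$window) && e$window$mode == "absence") {
          s
        } else {
          cand_intersect(s, cand(other))
        }
      },
      count = cand(e$arg),
      first_mention = cand(e$arg),
      original = cand(e$arg),
      diff = cand(e$args[[1L]]),
      export = cand(e$cohort),
      invert = NULL,
      no_history_of = NULL,
      never_had = NULL,
      not = NULL,
      NULL)
  }
  cand(expr)
}

#' Execute a TQL program over a patient store
#'
#' Parses (if given text), determines the candidate set from the feature
#' index, then fully evaluates each candidate patient.  The result maps each
#' matching patient (non-empty interval set) to the time intervals where the
#' query was true.
#'
#' @param program A `tql_program` or TQL source text.
#' @param store A `tql_store`.
#' @param use_index Use index-based candidate prefiltering (`TRUE`, the
#'   default) or evaluate every patient (the brute-force reference path).
#' @return A `tql_result` with `matches` (named list: patient id ->
#'   interval-set matrix), `n_candidates`, and the program.
#' @export
execute_query <- function(program, store, use_index = TRUE) {
  if (is.character(program)) program <- parse_tql(program)
  stopifnot(inherits(program, "tql_program"), inherits(store, "tql_store"))
  diags <- validate_program(program)
  if (length(diags)) {
    stop_eval(paste0("invalid program: ", paste(diags, collapse = "; ")))
  }
  idx <- if (use_index) {
    ids <- candidate_set(program$final, store, program$vars)
    if (is.null(ids)) seq_along(store$ids) else {
      i <- match(ids, store$ids)
      i[!is.na(i)]
    }
  } else {
    seq_along(store$ids)
  }
  out <- vector("list", length(idx))
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    p <- store$patients[[idx[j]]]
    m <- tryCatch(
      evaluate_patient(program$final, p, program$vars),
      tql_eval_error = function(c) {
        stop_eval(paste0("patient ", p$patient_id, ": ", conditionMessage(c)))
      })
    if (nrow(m) > 0L) { out[[j]] <- m; keep[j] <- TRUE }
  }
  matches <- out[keep]
  names(matches) <- store$ids[idx][keep]
  matches <- matches[order(names(matches))]
  cands <- idx
  structure(list(matches = matches, n_candidates = length(cands),
                 n_patients = length(store$ids), program = program),
            class = "tql_result")
}

#' @export
print.tql_result <- function(x, ...) {
  cat(sprintf("<query result> %d of %d patients matched (%d candidates evaluated)\n",
              length(x$matches), x$n_patients, x$n_candidates))
  invisible(x)
}

#' Matched patient ids of a result
#'
#' @param result A `tql_result`.
#' @return Sorted character vector of patient ids.
#' @export
matched_ids <- function(result) names(result$matches)

#' First day each matched patient satisfied the query
#'
#' @param result A `tql_result`.
#' @return A data frame with `patient_id`, `first_day`, `first_date`.
#' @export
first_satisfaction <- function(result) {
  ids <- matched_ids(result)
  days <- vapply(result$matches, function(m) m[1L, 1L], integer(1L))
  data.frame(patient_id = ids, first_day = as.integer(days),
             first_date = day_to_date(days), row.names = NULL,
             stringsAsFactors = FALSE)
}
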