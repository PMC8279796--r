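# Patient objects and the feature-indexed datastore ----------------------
#
# All the data of one patient live together in a patient object: attributes
# (birth day, gender, race/ethnicity), the observation-period span, and an
# event table keyed by feature keys of the form "NAMESPACE:code"
# (e.g. "ICD9:434.91", "RX:310490", "LOINC:4548-4 [%]", "TEXT:fever").
# Events carry the knowledge-graph-derived keys added at load time with
# original = FALSE.  A store groups patient objects and an inverted feature
# index (feature key -> patient ids) used for candidate prefiltering.

FEATURE_NAMESPACES <- c("ICD9", "ICD10", "CPT", "RX", "ATC", "LOINC",
                        "TEXT", "GENDER", "RACE", "VISIT", "NOTE_TYPE")

#' Compose a feature key
#'
#' @param namespace One of the supported namespaces (ICD9, ICD10, CPT, RX,
#'   ATC, LOINC, TEXT, GENDER, RACE, VISIT, NOTE_TYPE).
#' @param code Non-empty code string; compared by exact match within a
#'   namespace.
#' @return A string `"NAMESPACE:code"`.
#' @export
feature_key <- function(namespace, code) {
  namespace <- toupper(namespace)
  if (!all(namespace %in% FEATURE_NAMESPACES)) {
    stop("unknown feature namespace: ",
         paste(setdiff(namespace, FEATURE_NAMESPACES), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(code))) stop("feature code must be non-empty", call. = FALSE)
  paste0(namespace, ":", code)
}

empty_events <- function() {
  data.frame(key = character(0), start = integer(0), end = integer(0),
             value = numeric(0), negated = logical(0),
             family_history = logical(0), original = logical(0),
             stringsAsFactors = FALSE)
}

#' Build an event table
#'
#' @param key Feature keys (`"NAMESPACE:code"`).
#' @param start,end Half-open day-index bounds; `end` defaults to
#'   `start + 1` (point events).
#' @param value Numeric value, used for LOINC measurements; `NA` otherwise.
#' @param negated,family_history Mention flags, meaningful for TEXT events.
#' @param original `FALSE` for keys added by ontology expansion.
#' @return An event data frame.
#' @export
events_frame <- function(key, start, end = start + 1L, value = NA_real_,
                         negated = FALSE, family_history = FALSE,
                         original = TRUE) {
  n <- length(key)
  if (n == 0L) return(empty_events())
  data.frame(key = as.character(key), start = as.integer(start),
             end = as.integer(end), value = as.numeric(rep_len(value, n)),
             negated = rep_len(as.logical(negated), n),
             family_history = rep_len(as.logical(family_history), n),
             original = rep_len(as.logical(original), n),
             stringsAsFactors = FALSE)
}

# per-key canonical interval sets for fast selector evaluation
build_key_sets <- function(events) {
  if (nrow(events) == 0L) return(list())
  idx <- split(seq_len(nrow(events)), events$key)
  lapply(idx, function(i) coalesce_intervals(events$start[i], events$end[i]))
}

#' Construct a patient object
#'
#' Events are clipped to the observation span; events entirely outside the
#' span are dropped (with a warning when `warn_dropped`).
#'
#' @param patient_id Unique id string.
#' @param birth_day Day index of birth.
#' @param gender,race Demographic attribute strings (matched
#'   case-insensitively by GENDER/RACE selectors).
#' @param span Length-2 integer `c(start, end)`: the observation period as a
#'   half-open day interval.
#' @param events An event data frame from [events_frame()].
#' @param warn_dropped Warn when events fall entirely outside the span.
#' @return A `tql_patient` object.
#' @export
new_patient <- function(patient_id, birth_day, gender, race, span,
                        events = empty_events(), warn_dropped = FALSE) {
  span <- as.integer(span)
  stopifnot(length(span) == 2L, span[1L] < span[2L])
  if (nrow(events) > 0L) {
    s <- pmax(events$start, span[1L])
    e <- pmin(events$end, span[2L])
    keep <- s < e
    if (warn_dropped && !all(keep)) {
      warning(sprintf("patient %s: dropped %d event(s) outside observation span",
                      patient_id, sum(!keep)), call. = FALSE)
    }
    events <- events[keep, , drop = FALSE]
    events$start <- s[keep]
    events$end <- e[keep]
    rownames(events) <- NULL
  }
  p <- list(patient_id = as.character(patient_id),
            birth_day = as.integer(birth_day),
            gender = as.character(gender),
            race = as.character(race),
            span = span,
            events = events)
  p$key_sets <- build_key_sets(events)
  orig <- events[events$original, , drop = FALSE]
  p$key_sets_orig <- if (nrow(orig) == nrow(events)) p$key_sets else build_key_sets(orig)
  class(p) <- "tql_patient"
  p
}

#' @export
print.tql_patient <- function(x, ...) {
  cat(sprintf("<patient %s> %s/%s, born %s, span %s..%s, %d events (%d keys)\n",
              x$patient_id, x$gender, x$race, day_to_date(x$birth_day),
              day_to_date(x$span[1L]), day_to_date(x$span[2L]),
              nrow(x$events), length(x$key_sets)))
  invisible(x)
}

demographic_keys <- function(p) {
  c(paste0("GENDER:", tolower(p$gender)), paste0("RACE:", tolower(p$race)))
}

#' Build a feature-indexed patient store
#'
#' Groups patient objects and builds the inverted feature index: for every
#' feature key (including expansion-derived keys and lowercased GENDER/RACE
#' attribute keys), the set of patient ids having at least one event with
#' that key.
#'
#' @param patients A list of `tql_patient` objects with unique ids.
#' @param shards Optional character vector of shard labels (bookkeeping for
#'   stores reassembled from shard files).
#' @return A `tql_store` object.
#' @export
build_store <- function(patients, shards = "shard-0") {
  ids <- vapply(patients, `[[`, character(1L), "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(patients) <- ids
  key_list <- lapply(patients, function(p) c(names(p$key_sets), demographic_keys(p)))
  all_keys <- unlist(key_list, use.names = FALSE)
  all_ids <- rep(ids, lengths(key_list))
  index <- if (length(all_keys)) {
    list2env(split(all_ids, all_keys), hash = TRUE, size = max(29L, length(all_keys)))
  } else {
    new.env(hash = TRUE)
  }
  structure(list(patients = patients, ids = ids, index = index,
                 shards = shards, epoch = tql_epoch()),
            class = "tql_store")
}

#' @export
print.tql_store <- function(x, ...) {
  cat(sprintf("<patient store> %d patients, %d indexed feature keys, %d shard(s)\n",
              length(x$patients), length(ls(x$index)), length(x$shards)))
  invisible(x)
}

#' Look up a feature key in the store index
#'
#' @param store A `tql_store`.
#' @param key A feature key string (see [feature_key()]); unknown keys
#'   return the empty set.
#' @return Character vector of patient ids.
#' @export
index_lookup <- function(store, key) {
  v <- get0(key, envir = store$index, inherits = FALSE, ifnotfound = NULL)
  if (is.null(v)) character(0) else v
}

#' Feature keys present in a store's index
#'
#' @param store A `tql_store`.
#' @return Sorted character vector of indexed keys.
#' @export
index_keys <- function(store) sort(ls(store$index))
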