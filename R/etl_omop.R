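# OMOP CDM subset ETL ----------------------------------------------------
#
# Loads a directory of OMOP-CDM-v5.3-shaped CSV tables into patient objects.
# person and observation_period are mandatory; condition_occurrence,
# procedure_occurrence, drug_exposure, measurement and text_mention are
# optional.  Codes are taken from the *_source_value columns:
# condition_source_value carries a namespace prefix ("ICD9:434.91" or
# "ICD10:I63.9"), procedure_source_value a CPT code (bare or "CPT:"-
# prefixed), drug_source_value an RxCUI, measurement_source_value a LOINC
# code.  Dates are ISO-8601; OMOP end dates are inclusive, so an interval
# [start_date, end_date] becomes the half-open [start_day, end_day + 1).

stop_data <- function(msg) {
  stop(structure(class = c("tql_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

read_omop_table <- function(dir, name, required = FALSE) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) {
    if (required) stop_data(paste0("missing mandatory table: ", name, ".csv"))
    return(NULL)
  }
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = "person_id"),
                                        showProgress = FALSE))
  df$person_id <- as.character(df$person_id)
  df
}

parse_days <- function(x, file) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1L]
    stop_data(sprintf("%s: unparseable date '%s' (row %d)", file,
                      as.character(x)[bad], bad))
  }
  date_to_day(d)
}

check_persons <- function(df, file, known_ids) {
  if (is.null(df) || nrow(df) == 0L) return(invisible())
  orphan <- !(df$person_id %in% known_ids)
  if (any(orphan)) {
    stop_data(sprintf("%s: person_id %s (row %d) not present in person.csv",
                      file, df$person_id[which(orphan)[1L]], which(orphan)[1L]))
  }
  invisible()
}

split_prefixed_code <- function(x, default_ns, file) {
  x <- as.character(x)
  has_ns <- grepl("^[A-Za-z0-9_]+:", x)
  ns <- ifelse(has_ns, toupper(sub(":.*$", "", x)), default_ns)
  code <- ifelse(has_ns, sub("^[^:]*:", "", x), x)
  bad <- !(ns %in% FEATURE_NAMESPACES) | !nzchar(code)
  if (any(bad)) {
    stop_data(sprintf("%s: unusable source code '%s' (row %d)",
                      file, x[which(bad)[1L]], which(bad)[1L]))
  }
  paste0(ns, ":", code)
}

#' Load an OMOP CDM subset directory into a patient store
#'
#' @param dir Directory of OMOP-subset CSV files (`person.csv` and
#'   `observation_period.csv` mandatory).
#' @param ontologies Named list of `tql_ontology` objects (e.g. from
#'   [default_ontologies()]) used for load-time hierarchical expansion;
#'   `NULL` disables ICD expansion.
#' @param drug_map A `tql_drug_map` or `NULL`.
#' @param warn_dropped Warn about events outside the observation period.
#' @return A `tql_store`.
#' @export
load_omop <- function(dir, ontologies = NULL, drug_map = NULL,
                      warn_dropped = FALSE) {
  if (!dir.exists(dir)) stop_data(paste0("no such directory: ", dir))
  person <- read_omop_table(dir, "person", required = TRUE)
  obs <- read_omop_table(dir, "observation_period", required = TRUE)
  if (is.null(person) || nrow(person) == 0L) stop_data("person.csv is empty")
  if (anyDuplicated(person$person_id)) {
    stop_data(paste0("duplicate person_id in person.csv: ",
                     person$person_id[duplicated(person$person_id)][1L]))
  }
  ids <- person$person_id
  check_persons(obs, "observation_period.csv", ids)
  if (!all(ids %in% obs$person_id)) {
    stop_data(paste0("person without observation_period: ",
                     setdiff(ids, obs$person_id)[1L]))
  }

  # birth day from year/month/day columns (missing month/day default to 1)
  mo <- if ("month_of_birth" %in% names(person)) person$month_of_birth else 1L
  dy <- if ("day_of_birth" %in% names(person)) person$day_of_birth else 1L
  mo[is.na(mo)] <- 1L; dy[is.na(dy)] <- 1L
  birth <- parse_days(sprintf("%04d-%02d-%02d", person$year_of_birth, mo, dy),
                      "person.csv")
  gender <- as.character(person$gender_source_value)
  race <- if ("race_source_value" %in% names(person)) {
    as.character(person$race_source_value)
  } else rep("unknown", nrow(person))

  os <- parse_days(obs$observation_period_start_date, "observation_period.csv")
  oe <- parse_days(obs$observation_period_end_date, "observation_period.csv") + 1L
  span_start <- tapply(os, obs$person_id, min)
  span_end <- tapply(oe, obs$person_id, max)

  events_by_person <- rep(list(NULL), length(ids))
  names(events_by_person) <- ids
  add_events <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(invisible())
    chunks <- split(df[setdiff(names(df), "person_id")], df$person_id)
    for (pid in names(chunks)) {
      events_by_person[[pid]] <<- rbind(events_by_person[[pid]], chunks[[pid]])
    }
    invisible()
  }

  cond <- read_omop_table(dir, "condition_occurrence")
  if (!is.null(cond) && nrow(cond)) {
    check_persons(cond, "condition_occurrence.csv", ids)
    d <- parse_days(cond$condition_start_date, "condition_occurrence.csv")
    add_events(events_frame(
      split_prefixed_code(cond$condition_source_value, "ICD9",
                          "condition_occurrence.csv"),
      d) |> cbind(person_id = cond$person_id))
  }
  proc <- read_omop_table(dir, "procedure_occurrence")
  if (!is.null(proc) && nrow(proc)) {
    check_persons(proc, "procedure_occurrence.csv", ids)
    d <- parse_days(proc$procedure_date, "procedure_occurrence.csv")
    add_events(events_frame(
      split_prefixed_code(proc$procedure_source_value, "CPT",
                          "procedure_occurrence.csv"),
      d) |> cbind(person_id = proc$person_id))
  }
  drug <- read_omop_table(dir, "drug_exposure")
  if (!is.null(drug) && nrow(drug)) {
    check_persons(drug, "drug_exposure.csv", ids)
    ds <- parse_days(drug$drug_exposure_start_date, "drug_exposure.csv")
    de <- if ("drug_exposure_end_date" %in% names(drug)) {
      ee <- as.Date(as.character(drug$drug_exposure_end_date), format = "%Y-%m-%d")
      ifelse(is.na(ee), ds + 1L, date_to_day(ee) + 1L)
    } else ds + 1L
    de <- pmax(as.integer(de), ds + 1L)
    add_events(events_frame(
      paste0("RX:", as.character(drug$drug_source_value)), ds, de) |>
        cbind(person_id = drug$person_id))
  }
  meas <- read_omop_table(dir, "measurement")
  if (!is.null(meas) && nrow(meas)) {
    check_persons(meas, "measurement.csv", ids)
    d <- parse_days(meas$measurement_date, "measurement.csv")
    add_events(events_frame(
      paste0("LOINC:", as.character(meas$measurement_source_value)), d,
      value = as.numeric(meas$value_as_number)) |>
        cbind(person_id = meas$person_id))
  }
  text <- read_omop_table(dir, "text_mention")
  if (!is.null(text) && nrow(text)) {
    check_persons(text, "text_mention.csv", ids)
    d <- parse_days(text$note_date, "text_mention.csv")
    tf <- rbind(
      events_frame(paste0("TEXT:", as.character(text$phrase)), d,
                   negated = as.logical(text$negated),
                   family_history = as.logical(text$family_history)),
      events_frame(paste0("NOTE_TYPE:", as.character(text$note_type)), d))
    add_events(cbind(tf, person_id = rep(text$person_id, 2L)))
  }

  patients <- lapply(ids, function(pid) {
    ev <- events_by_person[[pid]]
    if (is.null(ev)) ev <- empty_events() else ev$person_id <- NULL
    p <- new_patient(pid, birth[match(pid, ids)], gender[match(pid, ids)],
                     race[match(pid, ids)],
                     c(span_start[[pid]], span_end[[pid]]), ev,
                     warn_dropped = warn_dropped)
    if (!is.null(ontologies) || !is.null(drug_map)) {
      p <- expand_events(p, ontologies, drug_map)
    }
    p
  })
  build_store(patients)
}

# shard files ------------------------------------------------------------

str_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 1000003
    as.integer(h)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Shard id a patient belongs to
#'
#' Deterministic partition by a polynomial hash of the patient id.
#' @param patient_id Character vector of ids.
#' @param n_shards Number of shards.
#' @return Integer shard indices in `0:(n_shards-1)`.
#' @export
shard_of <- function(patient_id, n_shards) str_hash(patient_id) %% n_shards

#' Write a store to a sharded on-disk layout
#'
#' Each shard is a self-contained pair of CSV files (`patients`, `events`,
#' post-expansion) that can be loaded independently; a JSON manifest lists
#' the shards, their patient counts and the epoch.
#'
#' @param store A `tql_store`.
#' @param dir Output directory (created if needed).
#' @param n_shards Number of shards (>= 1).
#' @return The manifest, invisibly.
#' @export
write_shards <- function(store, dir, n_shards = 1L) {
  stopifnot(n_shards >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_data(paste0("cannot create shard directory: ", dir))
  shard <- shard_of(store$ids, n_shards)
  counts <- integer(n_shards)
  for (k in seq_len(n_shards) - 1L) {
    pk <- store$patients[shard == k]
    counts[k + 1L] <- length(pk)
    pat_df <- do.call(rbind, lapply(pk, function(p) {
      data.frame(patient_id = p$patient_id, birth_day = p$birth_day,
                 gender = p$gender, race = p$race,
                 span_start = p$span[1L], span_end = p$span[2L],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pat_df)) {
      pat_df <- data.frame(patient_id = character(0), birth_day = integer(0),
                           gender = character(0), race = character(0),
                           span_start = integer(0), span_end = integer(0))
    }
    ev_df <- do.call(rbind, lapply(pk, function(p) {
      if (nrow(p$events) == 0L) return(NULL)
      cbind(data.frame(patient_id = p$patient_id, stringsAsFactors = FALSE),
            p$events)
    }))
    if (is.null(ev_df)) {
      ev_df <- cbind(data.frame(patient_id = character(0)), empty_events())
    }
    data.table::fwrite(pat_df, file.path(dir, sprintf("shard-%d-patients.csv", k)))
    data.table::fwrite(ev_df, file.path(dir, sprintf("shard-%d-events.csv", k)))
  }
  manifest <- list(format = "cohortql-shards-v1",
                   epoch = format(store$epoch),
                   n_shards = n_shards,
                   shards = lapply(seq_len(n_shards) - 1L, function(k) {
                     list(id = sprintf("shard-%d", k),
                          n_patients = counts[k + 1L])
                   }),
                   n_patients = length(store$ids))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a sharded store (fully or partially)
#'
#' @param dir Directory written by [write_shards()].
#' @param shards Shard ids (e.g. `c("shard-0", "shard-2")`) or `NULL` for
#'   all shards.
#' @return A `tql_store` containing exactly the selected shards' patients.
#' @export
load_shards <- function(dir, shards = NULL) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_data(paste0("no shard manifest in ", dir))
  manifest <- jsonlite::read_json(mpath)
  all_ids <- vapply(manifest$shards, `[[`, character(1L), "id")
  if (is.null(shards)) shards <- all_ids
  if (!all(shards %in% all_ids)) {
    stop_data(paste0("unknown shard id: ", setdiff(shards, all_ids)[1L]))
  }
  patients <- list()
  for (sid in shards) {
    pat <- as.data.frame(data.table::fread(
      file.path(dir, paste0(sid, "-patients.csv")),
      colClasses = list(character = c("patient_id", "gender", "race")),
      showProgress = FALSE))
    ev <- as.data.frame(data.table::fread(
      file.path(dir, paste0(sid, "-events.csv")),
      colClasses = list(character = c("patient_id", "key")),
      showProgress = FALSE))
    for (i in seq_len(nrow(pat))) {
      pid <- as.character(pat$patient_id[i])
      evi <- ev[ev$patient_id == pid, setdiff(names(ev), "patient_id"),
                drop = FALSE]
      if (nrow(evi) == 0L) {
        evi <- empty_events()
      } else {
        evi <- events_frame(evi$key, evi$start, evi$end, evi$value,
                            evi$negated, evi$family_history, evi$original)
      }
      patients[[length(patients) + 1L]] <-
        new_patient(pid, pat$birth_day[i], pat$gender[i], pat$race[i],
                    c(pat$span_start[i], pat$span_end[i]), evi)
    }
  }
  build_store(patients, shards = shards)
}
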