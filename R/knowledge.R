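# Knowledge-graph expansion ----------------------------------------------
#
# Hierarchical terminologies (ICD9, ICD10, ATC) are supplied as child,parent
# edge lists; drug exposures recorded as RxNorm RxCUIs map to ATC classes
# through an rxcui,atc table.  Expansion is applied once at load time: every
# coded event also deposits, at the same time point, one derived event per
# ancestor code (original = FALSE), so that a query for a parent code
# retrieves patients coded with any descendant.  The ORIGINAL command
# bypasses this by evaluating against original events only.

#' Load a code ontology from an edge list
#'
#' @param edges A data frame (or CSV path) with columns `child`, `parent`;
#'   each row is one is-a edge of the terminology DAG.
#' @param namespace Namespace of the codes (e.g. `"ICD9"`, `"ATC"`).
#' @return A `tql_ontology`: parent adjacency keyed by child code.
#' @export
load_ontology <- function(edges, namespace) {
  if (is.character(edges)) {
    edges <- utils::read.csv(edges, colClasses = "character")
  }
  if (!all(c("child", "parent") %in% names(edges))) {
    stop("ontology edge list needs columns child,parent", call. = FALSE)
  }
  parents <- lapply(split(as.character(edges$parent), as.character(edges$child)),
                    unique)
  ont <- structure(list(namespace = toupper(namespace), parents = parents),
                   class = "tql_ontology")
  assert_acyclic(ont)
  ont
}

assert_acyclic <- function(ont) {
  # iterative DFS with colors over the child -> parent graph
  color <- new.env(hash = TRUE)
  visit <- function(code) {
    stack <- list(c(code, "enter"))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      node <- top[1L]
      if (top[2L] == "exit") { assign(node, 2L, color); next }
      st <- get0(node, color, inherits = FALSE, ifnotfound = 0L)
      if (st == 1L) stop("cycle detected in ontology at code ", node, call. = FALSE)
      if (st == 2L) next
      assign(node, 1L, color)
      stack[[length(stack) + 1L]] <- c(node, "exit")
      for (p in ont$parents[[node]]) {
        pst <- get0(p, color, inherits = FALSE, ifnotfound = 0L)
        if (pst == 1L) stop("cycle detected in ontology at code ", p, call. = FALSE)
        if (pst == 0L) stack[[length(stack) + 1L]] <- c(p, "enter")
      }
    }
  }
  for (code in names(ont$parents)) visit(code)
  invisible(ont)
}

#' Ancestors of a code under transitive closure
#'
#' The transitive closure of the parent relation, excluding the code itself.
#' Unknown codes have no ancestors.
#'
#' @param ontology A `tql_ontology`.
#' @param code Code string.
#' @return Character vector of ancestor codes (unsorted set, deterministic
#'   order).
#' @export
ancestors <- function(ontology, code) {
  seen <- character(0)
  frontier <- ontology$parents[[code]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    if (!length(new)) break
    seen <- c(seen, new)
    frontier <- unique(unlist(ontology$parents[new], use.names = FALSE))
  }
  seen
}

#' Load an RxCUI to ATC drug-class map
#'
#' @param map A data frame (or CSV path) with columns `rxcui`, `atc`.
#' @param atc_ontology A `tql_ontology` over ATC codes used to add ancestor
#'   classes.
#' @return A `tql_drug_map`.
#' @export
load_drug_map <- function(map, atc_ontology) {
  if (is.character(map)) map <- utils::read.csv(map, colClasses = "character")
  if (!all(c("rxcui", "atc") %in% names(map))) {
    stop("drug map needs columns rxcui,atc", call. = FALSE)
  }
  structure(list(rx_to_atc = lapply(split(as.character(map$atc),
                                          as.character(map$rxcui)), unique),
                 atc_ontology = atc_ontology),
            class = "tql_drug_map")
}

#' Expand an RxCUI to its ATC classes
#'
#' The mapped ATC codes plus all their ATC ancestors; unmapped RxCUIs expand
#' to nothing.
#'
#' @param map A `tql_drug_map`.
#' @param rxcui RxCUI string.
#' @return Character vector of ATC codes.
#' @export
expand_drug <- function(map, rxcui) {
  atcs <- map$rx_to_atc[[as.character(rxcui)]]
  if (is.null(atcs)) return(character(0))
  up <- unlist(lapply(atcs, ancestors, ontology = map$atc_ontology),
               use.names = FALSE)
  unique(c(atcs, up))
}

#' Default fixture ontologies shipped with the package
#'
#' Small ICD9/ICD10/ATC fragments and an RxCUI-to-ATC map covering the codes
#' used by the canonical example queries and the synthetic-cohort generator.
#' Real vocabularies in the same edge-list format drop in via
#' [load_ontology()] / [load_drug_map()].
#'
#' @param dir Directory holding `icd9_edges.csv`, `icd10_edges.csv`,
#'   `atc_edges.csv`, `rx_to_atc.csv`; defaults to the package fixtures.
#' @return A list with elements `ICD9`, `ICD10` (ontologies) and `drug_map`.
#' @export
default_ontologies <- function(dir = system.file("extdata", "ontology",
                                                 package = "cohortql")) {
  atc <- load_ontology(file.path(dir, "atc_edges.csv"), "ATC")
  list(ICD9 = load_ontology(file.path(dir, "icd9_edges.csv"), "ICD9"),
       ICD10 = load_ontology(file.path(dir, "icd10_edges.csv"), "ICD10"),
       drug_map = load_drug_map(file.path(dir, "rx_to_atc.csv"), atc))
}

#' Add knowledge-graph-derived events to a patient
#'
#' For every original ICD9/ICD10 event, adds one event per ancestor code at
#' the same interval; for every original RX event, adds the mapped ATC
#' classes and their ancestors.  Derived events carry `original = FALSE` and
#' no measurement value.  Expansion is idempotent: derived events are
#' recomputed from the original events, never re-expanded.
#'
#' @param patient A `tql_patient`.
#' @param ontologies Named list of `tql_ontology` (names are namespaces,
#'   e.g. `ICD9`); may be `NULL`.
#' @param drug_map A `tql_drug_map` or `NULL`.
#' @return A new `tql_patient` including the derived events.
#' @export
expand_events <- function(patient, ontologies = NULL, drug_map = NULL) {
  ev <- patient$events
  orig <- ev[ev$original, , drop = FALSE]
  derived_list <- list()
  if (nrow(orig) > 0L) {
    ns <- sub(":.*$", "", orig$key)
    code <- sub("^[^:]*:", "", orig$key)
    for (i in seq_len(nrow(orig))) {
      new_keys <- character(0)
      if (ns[i] %in% c("ICD9", "ICD10") && !is.null(ontologies[[ns[i]]])) {
        anc <- ancestors(ontologies[[ns[i]]], code[i])
        if (length(anc)) new_keys <- paste0(ns[i], ":", anc)
      } else if (ns[i] == "RX" && !is.null(drug_map)) {
        atcs <- expand_drug(drug_map, code[i])
        if (length(atcs)) new_keys <- paste0("ATC:", atcs)
      }
      if (length(new_keys)) {
        derived_list[[length(derived_list) + 1L]] <-
          events_frame(new_keys, orig$start[i], orig$end[i], original = FALSE)
      }
    }
  }
  derived <- if (length(derived_list)) do.call(rbind, derived_list) else empty_events()
  derived <- unique(derived)
  new_patient(patient$patient_id, patient$birth_day, patient$gender,
              patient$race, patient$span, rbind(orig, derived))
}
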