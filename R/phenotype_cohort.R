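# Concept sets, descendant expansion against the ancestry table, and
# index-date cohorts (first-occurrence and high-sensitivity).

#' Create a concept set
#'
#' A named collection of concept ids with per-item `include_descendants` and
#' `is_excluded` flags, following the OHDSI concept-set expression shape.
#'
#' @param name set name.
#' @param items data.frame with columns `concept_id` and optionally
#'   `include_descendants`, `is_excluded` (both default `FALSE`).
#' @return object of class `concept_set`.
#' @export
concept_set <- function(name, items) {
  items <- as.data.frame(items)
  if (!nrow(items) || !"concept_id" %in% names(items))
    stop("a concept set needs >= 1 item with a concept_id column")
  if (!"include_descendants" %in% names(items))
    items$include_descendants <- FALSE
  if (!"is_excluded" %in% names(items)) items$is_excluded <- FALSE
  items <- data.frame(concept_id = as.integer(items$concept_id),
                      include_descendants = as.logical(items$include_descendants),
                      is_excluded = as.logical(items$is_excluded))
  structure(list(name = as.character(name), items = items),
            class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat("<concept_set> ", x$name, ": ", nrow(x$items), " item(s)\n", sep = "")
  invisible(x)
}

#' Expand a concept set against an ancestry table
#'
#' Included ids are the union over non-excluded items of the item itself
#' plus, when `include_descendants` is set, all its descendants per the
#' (reflexive) ancestry table. Excluded items are expanded the same way and
#' subtracted.
#'
#' @param cs a [concept_set()].
#' @param ancestry data.frame `(ancestor_concept_id, descendant_concept_id)`
#'   with reflexive rows present, e.g. `store$concept_ancestor`.
#' @return sorted integer vector of concept ids.
#' @export
expand_concept_set <- function(cs, ancestry) {
  stopifnot(inherits(cs, "concept_set"))
  ancestry <- data.table::as.data.table(ancestry)
  known <- unique(c(ancestry$ancestor_concept_id,
                    ancestry$descendant_concept_id))
  unknown <- setdiff(cs$items$concept_id, known)
  if (length(unknown))
    stop("concept set '", cs$name, "' references unknown concept id(s): ",
         paste(unknown, collapse = ", "))
  expand_side <- function(items) {
    if (!nrow(items)) return(integer(0))
    with_desc <- items$concept_id[items$include_descendants]
    bare <- items$concept_id[!items$include_descendants]
    desc <- ancestry[ancestor_concept_id %in% with_desc,
                     descendant_concept_id]
    unique(c(bare, with_desc, desc))
  }
  included <- expand_side(cs$items[!cs$items$is_excluded, , drop = FALSE])
  excluded <- expand_side(cs$items[cs$items$is_excluded, , drop = FALSE])
  sort(setdiff(included, excluded))
}

#' Read / write concept sets as JSON
#'
#' Uses the OHDSI concept-set expression shape: a list of objects with
#' `name` and `expression$items`, each item holding `concept$CONCEPT_ID`,
#' `includeDescendants`, `isExcluded`.
#'
#' @param path JSON file path.
#' @param concept_sets list of [concept_set()] objects.
#' @return list of concept sets (read) or the path (write).
#' @export
read_concept_sets <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(cs) {
    items <- do.call(rbind, lapply(cs$expression$items, function(it)
      data.frame(concept_id = it$concept$CONCEPT_ID,
                 include_descendants = isTRUE(it$includeDescendants),
                 is_excluded = isTRUE(it$isExcluded))))
    concept_set(cs$name, items)
  })
}

#' @rdname read_concept_sets
#' @export
write_concept_sets <- function(concept_sets, path) {
  payload <- lapply(concept_sets, function(cs) list(
    name = cs$name,
    expression = list(items = lapply(seq_len(nrow(cs$items)), function(i)
      list(concept = list(CONCEPT_ID = cs$items$concept_id[i]),
           includeDescendants = cs$items$include_descendants[i],
           isExcluded = cs$items$is_excluded[i])))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}

#' First-occurrence cohort for a phenotype algorithm
#'
#' The supported phenotype-algorithm skeleton: a person enters the cohort at
#' the date of their earliest event whose concept falls in the expanded
#' entry concept set and whose domain matches. Same-day ties are broken by
#' smallest concept_id (the index date is unaffected; the tie-break fixes
#' which event is deemed the entry event).
#'
#' @param store a [cdm_store()].
#' @param cs entry [concept_set()].
#' @param domain event domain of qualifying events (default `"condition"`).
#' @return data.table cohort `(person_id, index_date)`, sorted by person_id.
#' @export
first_occurrence_cohort <- function(store, cs, domain = "condition") {
  stopifnot(inherits(store, "cdm_store"))
  ids <- expand_concept_set(cs, store$concept_ancestor)
  ev <- store$event[store$event$domain == domain &
                      store$event$concept_id %in% ids]
  if (!nrow(ev))
    return(data.table::data.table(person_id = integer(),
                                  index_date = as.Date(character())))
  data.table::setorder(ev, person_id, event_date, concept_id)
  cohort <- ev[, .(index_date = event_date[1L]), by = person_id]
  data.table::setorder(cohort, person_id)
  cohort[]
}

#' High-sensitivity cohort: anyone with any related code
#'
#' A deliberately over-inclusive cohort intended to capture nearly all true
#' cases: every person with at least one event (any domain) in the union of
#' the expanded concept sets is eligible, and a seeded random sample without
#' replacement of `sample_size` eligible persons is returned. The index date
#' is the earliest qualifying event in the union (the natural analogue of
#' first occurrence for non-diagnosis entrants).
#'
#' @param store a [cdm_store()].
#' @param concept_sets list of [concept_set()] objects whose union defines
#'   eligibility.
#' @param sample_size number of persons to sample; capped at the eligible
#'   count with a warning.
#' @param seed integer sampling seed.
#' @return data.table cohort `(person_id, index_date)`, sorted by person_id.
#' @export
high_sensitivity_cohort <- function(store, concept_sets, sample_size,
                                    seed = 1L) {
  stopifnot(inherits(store, "cdm_store"), length(concept_sets) >= 1,
            sample_size >= 1)
  ids <- sort(unique(unlist(lapply(
    concept_sets, expand_concept_set, ancestry = store$concept_ancestor))))
  ev <- store$event[store$event$concept_id %in% ids]
  if (!nrow(ev)) stop("no person has any event in the concept-set union")
  data.table::setorder(ev, person_id, event_date, concept_id)
  eligible <- ev[, .(index_date = event_date[1L]), by = person_id]
  if (sample_size > nrow(eligible)) {
    warning("sample_size (", sample_size, ") exceeds eligible count (",
            nrow(eligible), "); returning all eligible persons")
    sample_size <- nrow(eligible)
  }
  set.seed(as.integer(seed))
  keep <- sort(sample(eligible$person_id, sample_size))
  cohort <- eligible[person_id %in% keep]
  data.table::setorder(cohort, person_id)
  cohort[]
}

#' Read / write cohorts as CSV
#'
#' @param cohort data.table `(person_id, index_date)`.
#' @param path CSV path.
#' @param cohort_name name recorded in the file.
#' @return path (write) or cohort (read).
#' @export
write_cohort <- function(cohort, path, cohort_name = "cohort") {
  out <- data.table::data.table(cohort_name = cohort_name,
                                person_id = cohort$person_id,
                                index_date = cohort$index_date)
  data.table::setorder(out, person_id)
  data.table::fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- data.table::fread(path, showProgress = FALSE)
  data.table::data.table(person_id = as.integer(x$person_id),
                         index_date = as_iso_date(x$index_date))
}
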