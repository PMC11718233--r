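#' @import data.table
#' @importFrom stats qbeta rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# Supported event domains and their OMOP v5.x table/column mapping.
# Tie-breaks over domains use this (alphabetical) order throughout.
.domains <- c("condition", "drug", "measurement", "observation", "procedure",
              "visit")

.domain_tables <- list(
  condition   = list(table = "condition_occurrence",
                     concept = "condition_concept_id",
                     date = "condition_start_date", has_value = FALSE),
  drug        = list(table = "drug_exposure",
                     concept = "drug_concept_id",
                     date = "drug_exposure_start_date", has_value = FALSE),
  measurement = list(table = "measurement",
                     concept = "measurement_concept_id",
                     date = "measurement_date", has_value = TRUE),
  observation = list(table = "observation",
                     concept = "observation_concept_id",
                     date = "observation_date", has_value = TRUE),
  procedure   = list(table = "procedure_occurrence",
                     concept = "procedure_concept_id",
                     date = "procedure_date", has_value = FALSE),
  visit       = list(table = "visit_occurrence",
                     concept = "visit_concept_id",
                     date = "visit_start_date", has_value = FALSE)
)

#' Assemble and validate an in-memory OMOP-shaped data bundle
#'
#' A `cdm_store` holds the minimal OMOP CDM v5.x subset the pipeline uses:
#' a person table, a unified longitudinal event table spanning the six
#' supported domains (condition, drug, measurement, observation, procedure,
#' visit), and a small vocabulary (concept + concept ancestry).
#'
#' Validation enforces referential integrity: every event's `person_id` must
#' exist in `person`, every event's `concept_id` must exist in `concept` with
#' a matching domain, and ancestry rows may only reference known concepts.
#' Reflexive ancestry rows (each concept its own descendant) are added if
#' absent so descendant expansion never special-cases self, and the
#' non-reflexive ancestry relation is checked to be acyclic.
#'
#' @param person data.frame with columns `person_id`, `year_of_birth`,
#'   `gender` (free text such as "FEMALE").
#' @param event data.frame with columns `person_id`, `concept_id`,
#'   `event_date` (`Date` or ISO-8601 text, day resolution), `domain`, and
#'   optionally `value_as_number`, `unit`.
#' @param concept data.frame with columns `concept_id`, `concept_name`,
#'   `domain`.
#' @param concept_ancestor data.frame with columns `ancestor_concept_id`,
#'   `descendant_concept_id`.
#' @return An object of class `cdm_store`.
#' @export
cdm_store <- function(person, event = NULL, concept = NULL,
                      concept_ancestor = NULL) {
  person <- as.data.table(person)
  req <- c("person_id", "year_of_birth", "gender")
  if (!all(req %in% names(person)))
    stop("person table must have columns: ", paste(req, collapse = ", "))
  person <- person[, ..req]
  person[, person_id := as.integer(person_id)]
  person[, year_of_birth := as.integer(year_of_birth)]
  person[, gender := as.character(gender)]
  if (anyDuplicated(person$person_id))
    stop("duplicate person_id in person table")

  if (is.null(concept))
    concept <- data.frame(concept_id = integer(), concept_name = character(),
                          domain = character())
  concept <- as.data.table(concept)[, .(concept_id = as.integer(concept_id),
                                        concept_name = as.character(concept_name),
                                        domain = tolower(as.character(domain)))]
  if (anyDuplicated(concept$concept_id))
    stop("duplicate concept_id in concept table")
  bad_dom <- setdiff(unique(concept$domain), .domains)
  if (length(bad_dom))
    stop("unsupported concept domain(s): ", paste(bad_dom, collapse = ", "))

  if (is.null(event))
    event <- data.frame(person_id = integer(), concept_id = integer(),
                        event_date = as.Date(character()), domain = character(),
                        value_as_number = numeric(), unit = character())
  event <- as.data.table(event)
  for (col in c("value_as_number", "unit"))
    if (!col %in% names(event))
      event[, (col) := if (col == "unit") NA_character_ else NA_real_]
  event <- event[, .(person_id = as.integer(person_id),
                     concept_id = as.integer(concept_id),
                     event_date = as_iso_date(event_date),
                     domain = tolower(as.character(domain)),
                     value_as_number = as.numeric(value_as_number),
                     unit = as.character(unit))]
  if (anyNA(event$event_date))
    stop("event table contains unparseable event_date values")
  if (nrow(event)) {
    missing_person <- setdiff(event$person_id, person$person_id)
    if (length(missing_person))
      stop("events reference unknown person_id(s): ",
           paste(head(missing_person, 10), collapse = ", "))
    lk <- merge(event[, .(concept_id, domain)],
                concept[, .(concept_id, cdomain = domain)],
                by = "concept_id", all.x = TRUE)
    dangling <- unique(lk[is.na(cdomain), concept_id])
    if (length(dangling))
      stop("events reference concept_id(s) absent from vocabulary: ",
           paste(head(dangling, 10), collapse = ", "))
    mismatch <- unique(lk[domain != cdomain, concept_id])
    if (length(mismatch))
      stop("event domain disagrees with vocabulary domain for concept_id(s): ",
           paste(head(mismatch, 10), collapse = ", "))
  }

  if (is.null(concept_ancestor))
    concept_ancestor <- data.frame(ancestor_concept_id = integer(),
                                   descendant_concept_id = integer())
  ca <- as.data.table(concept_ancestor)[
    , .(ancestor_concept_id = as.integer(ancestor_concept_id),
        descendant_concept_id = as.integer(descendant_concept_id))]
  unknown <- setdiff(unique(c(ca$ancestor_concept_id, ca$descendant_concept_id)),
                     concept$concept_id)
  if (length(unknown))
    stop("concept_ancestor references unknown concept_id(s): ",
         paste(head(unknown, 10), collapse = ", "))
  # reflexive closure: every concept is its own descendant
  ca <- unique(rbind(ca, data.table(ancestor_concept_id = concept$concept_id,
                                    descendant_concept_id = concept$concept_id)))
  assert_acyclic_ancestry(ca)

  setkey(person, person_id)
  setorder(event, person_id, event_date, domain, concept_id)
  setkey(concept, concept_id)
  setorder(ca, ancestor_concept_id, descendant_concept_id)
  structure(list(person = person, event = event, concept = concept,
                 concept_ancestor = ca),
            class = "cdm_store")
}

# Parses Date / ISO text to Date; non-ISO strings become NA (caller decides).
as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
}

# Topological-sort check on the strict (non-reflexive) ancestry relation.
assert_acyclic_ancestry <- function(ca) {
  edges <- ca[ancestor_concept_id != descendant_concept_id]
  nodes <- unique(c(edges$ancestor_concept_id, edges$descendant_concept_id))
  if (!length(nodes)) return(invisible(TRUE))
  indeg <- table(factor(edges$descendant_concept_id, levels = nodes))
  active <- setNames(as.integer(indeg), nodes)
  queue <- nodes[active == 0L]
  seen <- 0L
  adj <- split(edges$descendant_concept_id, factor(edges$ancestor_concept_id,
                                                   levels = nodes))
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in adj[[as.character(v)]]) {
      active[[as.character(w)]] <- active[[as.character(w)]] - 1L
      if (active[[as.character(w)]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes))
    stop("concept_ancestor contains a cycle")
  invisible(TRUE)
}

#' @export
print.cdm_store <- function(x, ...) {
  cat("<cdm_store>\n")
  cat("  persons:  ", nrow(x$person), "\n", sep = "")
  if (nrow(x$event)) {
    cnt <- x$event[, .N, by = domain][order(domain)]
    cat("  events:   ", nrow(x$event), " (",
        paste(sprintf("%s: %d", cnt$domain, cnt$N), collapse = ", "), ")\n",
        sep = "")
  } else cat("  events:   0\n")
  cat("  concepts: ", nrow(x$concept), "; ancestry rows: ",
      nrow(x$concept_ancestor), "\n", sep = "")
  invisible(x)
}

#' Read an OMOP-shaped table directory into a `cdm_store`
#'
#' Expects OMOP CDM v5.x table names (`person`, `concept`, `concept_ancestor`,
#' `condition_occurrence`, `drug_exposure`, `measurement`,
#' `procedure_occurrence`, `observation`, `visit_occurrence`) as `.csv`
#' (comma, UTF-8, header, ISO dates) or `.parquet` files. `person` and
#' `concept` are required; domain tables and `concept_ancestor` are optional.
#' Only the columns the pipeline uses are read; extra OMOP columns are
#' accepted and dropped with a message. OMOP `*_datetime` columns are ignored
#' (dates are day resolution).
#'
#' Rows with unparseable dates or concept ids missing from the vocabulary are
#' fatal by default; with `lenient = TRUE` they are dropped and reported.
#'
#' @param directory path containing the table files.
#' @param format `"csv"` or `"columnar"` (Parquet via the arrow package).
#' @param lenient drop-and-report bad rows instead of failing.
#' @return A validated [cdm_store()].
#' @export
read_cdm <- function(directory, format = c("csv", "columnar"),
                     lenient = FALSE) {
  format <- match.arg(format)
  ext <- if (format == "csv") ".csv" else ".parquet"
  read_tbl <- function(name, required = FALSE) {
    path <- file.path(directory, paste0(name, ext))
    if (!file.exists(path)) {
      if (required) stop("required table file not found: ", path)
      return(NULL)
    }
    if (format == "csv") {
      as.data.table(fread(path, showProgress = FALSE))
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("columnar format requires the 'arrow' package")
      as.data.table(arrow::read_parquet(path))
    }
  }
  person_raw <- read_tbl("person", required = TRUE)
  concept_raw <- read_tbl("concept", required = TRUE)
  ca_raw <- read_tbl("concept_ancestor")

  take <- function(tbl, cols, table_name) {
    missing <- setdiff(cols, names(tbl))
    if (length(missing))
      stop(table_name, " is missing column(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(names(tbl), cols)
    if (length(extra))
      message(table_name, ": ignoring extra column(s) ",
              paste(extra, collapse = ", "))
    tbl[, ..cols]
  }
  person <- take(person_raw,
                 c("person_id", "year_of_birth", "gender_source_value"),
                 "person")
  setnames(person, "gender_source_value", "gender")
  concept <- take(concept_raw, c("concept_id", "concept_name", "domain_id"),
                  "concept")
  setnames(concept, "domain_id", "domain")
  if (!is.null(ca_raw))
    ca_raw <- take(ca_raw, c("ancestor_concept_id", "descendant_concept_id"),
                   "concept_ancestor")

  events <- list()
  dropped <- list()
  for (dom in .domains) {
    mp <- .domain_tables[[dom]]
    tbl <- read_tbl(mp$table)
    if (is.null(tbl)) next
    cols <- c("person_id", mp$concept, mp$date)
    if (mp$has_value)
      cols <- c(cols, intersect(c("value_as_number", "unit_source_value"),
                                names(tbl)))
    tbl <- take(tbl, cols, mp$table)
    ev <- data.table(person_id = as.integer(tbl$person_id),
                     concept_id = as.integer(tbl[[mp$concept]]),
                     event_date = as_iso_date(tbl[[mp$date]]),
                     domain = dom)
    ev[, value_as_number := if ("value_as_number" %in% names(tbl))
      as.numeric(tbl$value_as_number) else NA_real_]
    ev[, unit := if ("unit_source_value" %in% names(tbl))
      as.character(tbl$unit_source_value) else NA_character_]
    ev[!is.na(unit) & unit == "", unit := NA_character_]  # CSV empty cell
    bad <- is.na(ev$event_date)
    if (any(bad)) {
      if (!lenient)
        stop(mp$table, ": ", sum(bad), " row(s) with unparseable dates; ",
             "use lenient = TRUE to drop them")
      dropped[[dom]] <- sum(bad)
      ev <- ev[!bad]
    }
    if (lenient && nrow(ev)) {
      dangling <- !ev$concept_id %in% concept$concept_id
      if (any(dangling)) {
        dropped[[dom]] <- sum(dangling) + (dropped[[dom]] %||% 0L)
        ev <- ev[!dangling]
      }
    }
    events[[dom]] <- ev
    message(mp$table, ": ", nrow(ev), " row(s)")
  }
  if (length(dropped))
    message("lenient mode dropped rows: ",
            paste(sprintf("%s=%d", names(dropped), unlist(dropped)),
                  collapse = ", "))
  event <- if (length(events)) rbindlist(events) else NULL
  cdm_store(person = person, event = event, concept = concept,
            concept_ancestor = ca_raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a `cdm_store` to OMOP-shaped table files
#'
#' Tables are written with a stable column order and a stable row order
#' (person_id, date, concept_id), so identical stores produce byte-identical
#' files. Empty domains still produce a header-only file, and reflexive
#' ancestry rows are written as stored.
#'
#' @param store a [cdm_store()].
#' @param directory output path (created if needed).
#' @param format `"csv"` or `"columnar"` (Parquet via arrow).
#' @return Invisibly, a data.frame manifest of `(table, path, n_rows)`.
#' @export
write_cdm <- function(store, directory, format = c("csv", "columnar")) {
  stopifnot(inherits(store, "cdm_store"))
  format <- match.arg(format)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  ext <- if (format == "csv") ".csv" else ".parquet"
  write_tbl <- function(tbl, name) {
    path <- file.path(directory, paste0(name, ext))
    if (format == "csv") {
      fwrite(tbl, path, dateTimeAs = "ISO")
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop("columnar format requires the 'arrow' package")
      arrow::write_parquet(tbl, path)
    }
    data.frame(table = name, path = path, n_rows = nrow(tbl))
  }
  manifest <- list()
  p <- copy(store$person)[order(person_id)]
  setnames(p, "gender", "gender_source_value")
  manifest$person <- write_tbl(p, "person")
  cc <- copy(store$concept)[order(concept_id)]
  setnames(cc, "domain", "domain_id")
  manifest$concept <- write_tbl(cc, "concept")
  ca <- store$concept_ancestor[order(ancestor_concept_id,
                                     descendant_concept_id)]
  manifest$concept_ancestor <- write_tbl(ca, "concept_ancestor")
  for (dom in .domains) {
    mp <- .domain_tables[[dom]]
    ev <- store$event[domain == dom][order(person_id, event_date, concept_id)]
    out <- data.table(person_id = ev$person_id)
    out[[mp$concept]] <- ev$concept_id
    out[[mp$date]] <- format(ev$event_date, "%Y-%m-%d")
    if (mp$has_value) {
      out[["value_as_number"]] <- ev$value_as_number
      out[["unit_source_value"]] <- ev$unit
    }
    manifest[[mp$table]] <- write_tbl(out, mp$table)
  }
  invisible(do.call(rbind, unname(manifest)))
}

#' Ordered events for one person
#'
#' Returns the person's events (optionally restricted to a set of domains)
#' sorted ascending by `(event_date, domain, concept_id)`; domains order
#' alphabetically. An unknown person is an error, distinct from a known
#' person with zero events (empty table).
#'
#' @param store a [cdm_store()].
#' @param person_id integer person id.
#' @param domains optional character vector of domains to keep.
#' @return data.table of events.
#' @export
events_for_person <- function(store, person_id, domains = NULL) {
  stopifnot(inherits(store, "cdm_store"))
  pid <- as.integer(person_id)
  if (!pid %in% store$person$person_id)
    stop("unknown person_id: ", person_id)
  ev <- store$event[store$event$person_id == pid]
  if (!is.null(domains)) {
    bad <- setdiff(domains, .domains)
    if (length(bad)) stop("unknown domain(s): ", paste(bad, collapse = ", "))
    ev <- ev[ev$domain %in% domains]
  }
  ev[order(event_date, domain, concept_id)]
}
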