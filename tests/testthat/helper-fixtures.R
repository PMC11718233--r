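# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive per-row loops and base-R set operations, independent of the
# data.table paths they check.

tiny_vocab <- function() {
  concept <- data.frame(
    concept_id = c(10L, 11L, 12L, 20L, 30L, 40L, 50L, 60L),
    concept_name = c("Root disease", "Subtype A", "Subtype B", "Symptom X",
                     "Drug Y", "Lab Z", "Procedure P", "Other condition"),
    domain = c("condition", "condition", "condition", "condition", "drug",
               "measurement", "procedure", "condition"))
  ancestry <- data.frame(ancestor_concept_id = c(10L, 10L),
                         descendant_concept_id = c(11L, 12L))
  list(concept = concept, ancestry = ancestry)
}

tiny_store <- function() {
  v <- tiny_vocab()
  person <- data.frame(person_id = 1:3, year_of_birth = c(1950L, 1960L, 1970L),
                       gender = c("FEMALE", "MALE", "FEMALE"))
  event <- data.frame(
    person_id = c(1L, 1L, 1L, 2L, 2L, 3L),
    concept_id = c(20L, 11L, 30L, 12L, 60L, 40L),
    event_date = as.Date(c("2016-03-01", "2016-03-10", "2016-03-20",
                           "2017-06-05", "2017-06-05", "2018-01-15")),
    domain = c("condition", "condition", "drug", "condition", "condition",
               "measurement"),
    value_as_number = c(NA, NA, NA, NA, NA, 7.5),
    unit = c(NA, NA, NA, NA, NA, "mg"))
  cdm_store(person = person, event = event, concept = v$concept,
            concept_ancestor = v$ancestry)
}

# Random small store over the tiny vocabulary (events drawn uniformly with
# dates in a one-year window).
random_store <- function(seed, n_persons = 5, n_events = 25) {
  set.seed(seed)
  v <- tiny_vocab()
  person <- data.frame(person_id = seq_len(n_persons),
                       year_of_birth = sample(1940:1990, n_persons,
                                              replace = TRUE),
                       gender = sample(c("FEMALE", "MALE"), n_persons,
                                       replace = TRUE))
  idx <- sample(nrow(v$concept), n_events, replace = TRUE)
  event <- data.frame(
    person_id = sample(n_persons, n_events, replace = TRUE),
    concept_id = v$concept$concept_id[idx],
    event_date = as.Date("2016-01-01") + sample(0:365, n_events,
                                                replace = TRUE),
    domain = v$concept$domain[idx],
    value_as_number = ifelse(v$concept$domain[idx] == "measurement" &
                               runif(n_events) < 0.5,
                             round(runif(n_events, 1, 100), 1), NA),
    unit = NA_character_)
  cdm_store(person = person, event = event, concept = v$concept,
            concept_ancestor = v$ancestry)
}

# Brute-force filter-and-sort oracle for events_for_person.
oracle_events_for_person <- function(store, pid, domains = NULL) {
  ev <- as.data.frame(store$event)
  ev <- ev[ev$person_id == pid, ]
  if (!is.null(domains)) ev <- ev[ev$domain %in% domains, ]
  ev[order(ev$event_date, ev$domain, ev$concept_id), ]
}

# Brute-force transitive-reflexive closure by repeated edge joining.
oracle_closure <- function(concept_ids, edges) {
  pairs <- unique(rbind(data.frame(a = concept_ids, d = concept_ids),
                        data.frame(a = edges$ancestor_concept_id,
                                   d = edges$descendant_concept_id)))
  repeat {
    joined <- merge(pairs, pairs, by.x = "d", by.y = "a")
    new_pairs <- unique(rbind(pairs, data.frame(a = joined$a,
                                                d = joined$d.y)))
    if (nrow(new_pairs) == nrow(pairs)) break
    pairs <- new_pairs
  }
  pairs[order(pairs$a, pairs$d), ]
}

# Brute-force reachability for concept-set expansion over an ancestry table.
oracle_expand <- function(cs, ancestry) {
  reach <- function(items) {
    out <- integer(0)
    for (i in seq_len(nrow(items))) {
      id <- items$concept_id[i]
      out <- c(out, id)
      if (items$include_descendants[i])
        out <- c(out, ancestry$descendant_concept_id[
          ancestry$ancestor_concept_id == id])
    }
    unique(out)
  }
  inc <- reach(cs$items[!cs$items$is_excluded, , drop = FALSE])
  exc <- reach(cs$items[cs$items$is_excluded, , drop = FALSE])
  sort(setdiff(inc, exc))
}

# Brute-force per-person min-date scan for first-occurrence cohorts.
oracle_first_occurrence <- function(store, ids, domain) {
  ev <- as.data.frame(store$event)
  ev <- ev[ev$domain == domain & ev$concept_id %in% ids, ]
  out <- do.call(rbind, lapply(split(ev, ev$person_id), function(g)
    data.frame(person_id = g$person_id[1], index_date = min(g$event_date))))
  if (is.null(out))
    return(data.frame(person_id = integer(),
                      index_date = as.Date(character())))
  out[order(out$person_id), ]
}

# Brute-force triple filter (concept in set, domain match, window) for one
# profile category.
oracle_category_items <- function(store, pid, index_date, ids, domains,
                                  lo, hi) {
  ev <- as.data.frame(store$event)
  ev <- ev[ev$person_id == pid & ev$concept_id %in% ids &
             ev$domain %in% domains, ]
  d <- as.integer(ev$event_date - index_date)
  ev <- ev[d >= lo & d <= hi, ]
  # collapse duplicates like the implementation documents
  unique(ev[, c("concept_id", "event_date")])
}

# Independent token-based oracle for the response parser: tokenizes on
# word characters, finds the last "summary" token, and scans tokens from
# there (or the last 200 characters when absent).
oracle_parse <- function(raw) {
  raw <- paste(as.character(raw), collapse = "\n")
  m <- gregexpr("[[:alnum:]_]+", raw)[[1]]
  toks <- if (m[1] == -1) character(0) else
    regmatches(raw, list(m))[[1]]
  hits <- which(tolower(toks) == "summary")
  seg <- if (length(hits)) substring(raw, m[hits[length(hits)]])
  else substring(raw, max(1, nchar(raw) - 199))
  sm <- gregexpr("[[:alnum:]_]+", seg)[[1]]
  words <- if (sm[1] == -1) character(0) else
    tolower(regmatches(seg, list(sm))[[1]])
  y <- "yes" %in% words
  n <- "no" %in% words
  if (y && !n) "yes" else if (n && !y) "no" else "indeterminate"
}

# Independent reimplementation of the mock decision rule, reading the
# serialized profile text directly.
oracle_mock_decision <- function(profile_text, min_support = 2,
                                 veto = TRUE) {
  lines <- strsplit(profile_text, "\n")[[1]]
  groups <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl(":$", ln)) { cur <- sub(":$", "", ln); groups[[cur]] <- 0 }
    else if (!is.null(cur) && grepl("^- ", ln) && ln != "- none recorded")
      groups[[cur]] <- groups[[cur]] + 1
  }
  supp <- c("Diagnoses recorded prior to the visit",
            "Laboratory tests and measurements",
            "Treatments recorded after the visit",
            "Complications recorded after the visit")
  counts <- unlist(groups[names(groups) %in% supp])
  n_groups <- sum(counts > 0)
  n_items <- sum(counts)
  n_diff <- groups[["Alternative diagnoses recorded around the visit"]]
  n_diff <- if (is.null(n_diff)) 0 else n_diff
  dec <- n_groups >= min_support
  if (dec && veto && n_diff > n_items) dec <- FALSE
  if (dec) "yes" else "no"
}

# A small random patient_profile over the default categories.
random_profile <- function(seed) {
  set.seed(seed)
  cats <- c("clinical_presentation", "disease_history",
            "preliminary_diagnosis", "diagnostic_procedures",
            "differential_diagnoses", "treatment", "comorbidities")
  n <- sample(0:8, 1)
  items <- if (n > 0) {
    data.table::data.table(
      category = sample(cats, n, replace = TRUE),
      concept_id = sample(100:999, n),
      concept_name = paste("Concept", sample(LETTERS, n, replace = TRUE),
                           sample(99, n)),
      event_date = as.Date("2016-06-01") + sample(-120:120, n,
                                                  replace = TRUE),
      days_from_index = 0L, domain = "condition",
      value_as_number = NA_real_, unit = NA_character_,
      n_occurrences = sample(1:3, n, replace = TRUE))
  } else {
    data.table::data.table(
      category = character(), concept_id = integer(),
      concept_name = character(), event_date = as.Date(character()),
      days_from_index = integer(), domain = character(),
      value_as_number = numeric(), unit = character(),
      n_occurrences = integer())
  }
  if (nrow(items))
    items$days_from_index <- as.integer(items$event_date -
                                          as.Date("2016-06-01"))
  structure(list(person_id = sample(1000L:9999L, 1),
                 index_date = as.Date("2016-06-01"),
                 age_at_index = sample(20:90, 1),
                 gender = sample(c("FEMALE", "MALE"), 1),
                 disease_name = "test disease",
                 categories = cats,
                 items = items[order(match(category, cats), event_date,
                                     concept_name)]),
            class = "patient_profile")
}
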