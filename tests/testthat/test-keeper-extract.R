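make_window_store <- function(days, domain = "condition",
                              concept_id = 20L) {
  # one person, events at given day offsets from 2016-06-01
  v <- tiny_vocab()
  idx <- as.Date("2016-06-01")
  event <- data.frame(person_id = 1L, concept_id = concept_id,
                      event_date = idx + days,
                      domain = domain, value_as_number = NA_real_,
                      unit = NA_character_)
  store <- cdm_store(data.frame(person_id = 1L, year_of_birth = 1950L,
                                gender = "FEMALE"),
                     event, v$concept, v$ancestry)
  list(store = store, entry = data.frame(person_id = 1L, index_date = idx))
}

test_that("window bounds are inclusive at both ends", {
  w <- make_window_store(c(-31L, -30L, 0L, 1L))
  config <- keeper_config("d", "def", list(
    keeper_category("clinical_presentation",
                    concept_set("s", data.frame(concept_id = 20L)),
                    "condition", -30, 0)))
  prof <- extract_profile(w$store, w$entry, config)
  expect_equal(sort(prof$items$days_from_index), c(-30L, 0L))
})

test_that("an unbounded window start reaches any time strictly prior", {
  w <- make_window_store(c(-900L, -1L, 0L))
  config <- keeper_config("d", "def", list(
    keeper_category("comorbidities",
                    concept_set("c", data.frame(concept_id = 20L)),
                    "condition", -Inf, -1)))
  prof <- extract_profile(w$store, w$entry, config)
  expect_equal(sort(prof$items$days_from_index), c(-900L, -1L))
})

test_that("inverted windows, unknown categories and empty sets are fatal", {
  cs <- concept_set("s", data.frame(concept_id = 20L))
  expect_error(keeper_category("clinical_presentation", cs, "condition",
                               10, -10), "start_offset")
  expect_error(keeper_category("nonsense_category", cs, "condition",
                               -30, 0), "unknown category_name")
  expect_error(keeper_category("treatment", cs, "martian", 0, 90),
               "unknown domain")
  expect_error(
    keeper_config("d", "def", list(
      keeper_category("treatment", cs, "drug", 0, 90),
      keeper_category("treatment", cs, "drug", 0, 30))),
    "duplicate category names")
})

test_that("configs round-trip through YAML and JSON including -Inf", {
  config <- template_keeper_config(osteoporosis_template())
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    save_keeper_config(config, path)
    back <- load_keeper_config(path)
    expect_equal(back, config, label = ext)
  }
})

test_that("the shipped illustrative configs load and validate", {
  for (f in c("osteoporosis_keeper_config.yaml",
              "rheumatoid_arthritis_keeper_config.yaml")) {
    path <- system.file("extdata", f, package = "keeperllm")
    expect_true(nzchar(path), label = f)
    cfg <- load_keeper_config(path)
    expect_s3_class(cfg, "keeper_config")
    # symptoms are extracted from the 30 days before index
    cp <- cfg$categories[[which(vapply(cfg$categories, `[[`, character(1),
                                       "category_name") ==
                                  "clinical_presentation")]]
    expect_equal(c(cp$start_offset_days, cp$end_offset_days), c(-30, 0))
  }
  sets <- read_concept_sets(system.file(
    "extdata", "osteoporosis_concept_sets.json", package = "keeperllm"))
  expect_length(sets, 2)
  expect_true(sets[[1]]$items$include_descendants[1])
})

test_that("duplicate billing rows collapse to one item with a count", {
  w <- make_window_store(c(-5L, -5L, -5L, -2L))
  config <- keeper_config("d", "def", list(
    keeper_category("clinical_presentation",
                    concept_set("s", data.frame(concept_id = 20L)),
                    "condition", -30, 0)))
  prof <- extract_profile(w$store, w$entry, config)
  expect_equal(nrow(prof$items), 2)
  expect_equal(prof$items$n_occurrences[prof$items$days_from_index == -5L],
               3L)
})

test_that("extraction matches the brute-force triple filter on random stores", {
  cats <- list(
    list(name = "clinical_presentation", ids_root = 20L, desc = FALSE,
         domains = "condition", lo = -30, hi = 0),
    list(name = "disease_history", ids_root = 10L, desc = TRUE,
         domains = "condition", lo = -Inf, hi = -1),
    list(name = "diagnostic_procedures", ids_root = 40L, desc = FALSE,
         domains = "measurement", lo = -30, hi = 30),
    list(name = "treatment", ids_root = 30L, desc = FALSE,
         domains = "drug", lo = 0, hi = 90))
  config <- keeper_config("d", "def", lapply(cats, function(cc)
    keeper_category(cc$name,
                    concept_set(cc$name,
                                data.frame(concept_id = cc$ids_root,
                                           include_descendants = cc$desc)),
                    cc$domains, cc$lo, cc$hi)))
  for (seed in 101:140) {
    store <- random_store(seed, n_persons = 4, n_events = 30)
    pid <- sample(store$person$person_id, 1)
    idx <- as.Date("2016-06-01") + sample(-60:60, 1)
    prof <- extract_profile(store,
                            list(person_id = pid, index_date = idx),
                            config)
    for (cc in cats) {
      ids <- expand_concept_set(
        concept_set("x", data.frame(concept_id = cc$ids_root,
                                    include_descendants = cc$desc)),
        store$concept_ancestor)
      want <- oracle_category_items(store, pid, idx, ids, cc$domains,
                                    cc$lo, cc$hi)
      got <- prof$items[prof$items$category == cc$name, ]
      expect_equal(nrow(got), nrow(want))
      key <- function(x) sort(paste(x$concept_id, x$event_date))
      expect_equal(key(got), key(want))
    }
  }
})

test_that("extraction invariants hold over simulated cohorts", {
  tpl <- osteoporosis_template()
  sim <- simulate_population(tpl, simulation_params(n_persons = 120,
                                                    seed = 13))
  config <- template_keeper_config(tpl)
  cs <- concept_set("dx", data.frame(concept_id = unname(tpl$diagnosis_root),
                                     include_descendants = TRUE))
  cohort <- first_occurrence_cohort(sim$store, cs)
  profiles <- extract_profiles(sim$store, cohort, config)
  expect_length(profiles, nrow(cohort))
  windows <- lapply(config$categories, function(cc)
    c(cc$start_offset_days, cc$end_offset_days))
  names(windows) <- vapply(config$categories, `[[`, character(1),
                           "category_name")
  sets <- lapply(config$categories, function(cc)
    expand_concept_set(cc$concept_set, sim$store$concept_ancestor))
  names(sets) <- names(windows)
  for (p in profiles) {
    expect_equal(p$person_id,
                 cohort$person_id[match(p$person_id, cohort$person_id)])
    if (!nrow(p$items)) next
    for (i in seq_len(nrow(p$items))) {
      ct <- p$items$category[i]
      d <- p$items$days_from_index[i]
      expect_gte(d, windows[[ct]][1])
      expect_lte(d, windows[[ct]][2])
      expect_true(p$items$concept_id[i] %in% sets[[ct]])
    }
    # dates never precede birth year
    expect_true(all(as.integer(format(p$items$event_date, "%Y")) >=
                      sim$store$person$year_of_birth[
                        sim$store$person$person_id == p$person_id]))
  }
  # partition: per-profile items together equal one global extraction pass
  n_items <- sum(vapply(profiles, function(p) sum(p$items$n_occurrences),
                        numeric(1)))
  global <- 0
  ev <- as.data.frame(sim$store$event)
  for (k in seq_along(config$categories)) {
    cc <- config$categories[[k]]
    for (j in seq_len(nrow(cohort))) {
      keep <- ev$person_id == cohort$person_id[j] &
        ev$concept_id %in% sets[[k]] & ev$domain %in% cc$domains
      d <- as.integer(ev$event_date - cohort$index_date[j])
      global <- global + sum(keep & d >= cc$start_offset_days &
                               d <= cc$end_offset_days)
    }
  }
  expect_equal(n_items, global)
})

test_that("profiles round-trip through JSONL", {
  tpl <- osteoporosis_template()
  sim <- simulate_population(tpl, simulation_params(n_persons = 40,
                                                    seed = 21))
  config <- template_keeper_config(tpl)
  cs <- concept_set("dx", data.frame(concept_id = unname(tpl$diagnosis_root),
                                     include_descendants = TRUE))
  cohort <- first_occurrence_cohort(sim$store, cs)
  profiles <- extract_profiles(sim$store, cohort, config)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_profiles(profiles, path)
  back <- read_profiles(path)
  expect_equal(length(back), length(profiles))
  for (i in seq_along(profiles)) {
    expect_equal(back[[i]]$person_id, profiles[[i]]$person_id)
    expect_equal(back[[i]]$index_date, profiles[[i]]$index_date)
    expect_equal(as.data.frame(back[[i]]$items),
                 as.data.frame(profiles[[i]]$items))
  }
})
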