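test_that("profile serialization is deterministic and group-complete", {
  p <- random_profile(1)
  a <- serialize_profile(p)
  b <- serialize_profile(p)
  expect_identical(a, b)
  groups <- unique(unname(default_profile_grouping()[p$categories]))
  for (g in groups) expect_match(a, paste0(g, ":"), fixed = TRUE)
})

test_that("symptom items render under the prior-diagnoses display group", {
  p <- random_profile(2)
  p$items <- data.table::data.table(
    category = "clinical_presentation", concept_id = 2001L,
    concept_name = "Joint pain of pelvic region",
    event_date = as.Date("2016-05-20"), days_from_index = -12L,
    domain = "condition", value_as_number = NA_real_,
    unit = NA_character_, n_occurrences = 1L)
  txt <- serialize_profile(p)
  lines <- strsplit(txt, "\n")[[1]]
  hdr <- which(lines == "Diagnoses recorded prior to the visit:")
  expect_equal(lines[hdr + 1],
               "- Joint pain of pelvic region (day -12)")
  # all other groups report explicit absence
  expect_equal(sum(lines == "- none recorded"),
               length(unique(unname(
                 default_profile_grouping()[p$categories]))) - 1)
})

test_that("measurements render values or an explicit not-recorded marker", {
  p <- random_profile(3)
  p$items <- data.table::data.table(
    category = "diagnostic_procedures", concept_id = c(4001L, 4002L),
    concept_name = c("Lab A", "Lab B"),
    event_date = as.Date("2016-06-01") + c(1, 2),
    days_from_index = c(1L, 2L), domain = "measurement",
    value_as_number = c(42.5, NA), unit = c("mg", NA),
    n_occurrences = c(1L, 2L))
  txt <- serialize_profile(p)
  expect_match(txt, "- Lab A (day 1; value 42.5 mg)", fixed = TRUE)
  expect_match(txt, "- Lab B (day 2; result not recorded; recorded 2 times)",
               fixed = TRUE)
})

test_that("uncovered categories are fatal", {
  p <- random_profile(4)
  grouping <- default_profile_grouping()
  grouping <- grouping[names(grouping) != "treatment"]
  expect_error(serialize_profile(p, grouping), "does not cover")
})

test_that("system prompts compose cumulatively and monotonically", {
  variants <- prompt_variants()
  prompts <- vapply(variants, build_system_prompt, character(1),
                    disease_name = "osteoporosis")
  # V0 has the yes/no + Summary instruction and no staged parts
  expect_match(prompts[1], "Summary")
  expect_match(prompts[1], "osteoporosis")
  expect_no_match(prompts[1], "evidence")
  # strict growth through V4
  for (k in 2:5) {
    expect_gt(nchar(prompts[k]), nchar(prompts[k - 1]))
    expect_true(startsWith(prompts[k], prompts[k - 1]))
  }
  # sentence-level monotonicity: every sentence of V_k appears in V_m, k<m
  sentences <- function(x) setdiff(trimws(strsplit(x, "(?<=\\.)\\s+",
                                                   perl = TRUE)[[1]]), "")
  for (k in 1:4) for (m in (k + 1):5) {
    expect_true(all(sentences(prompts[k]) %in% sentences(prompts[m])))
  }
  # V5 adds no system text beyond V4 (examples travel as messages)
  expect_identical(unname(prompts[6]), unname(prompts[5]))
  # the four parts appear in order in the full prompt
  pos <- c(regexpr("discuss the evidence", prompts[5]),
           regexpr("clinical narrative", prompts[5]),
           regexpr("alone is not sufficient", prompts[5]),
           regexpr("uncertain", prompts[5]))
  expect_true(all(pos > 0) && all(diff(pos) > 0))
})

test_that("message lists have the documented order and cardinality", {
  txt <- serialize_profile(random_profile(5))
  m4 <- build_messages(txt, "osteoporosis", "a skeletal disorder",
                       "V4_uncertainty")
  expect_length(m4, 2)
  expect_equal(vapply(m4, `[[`, character(1), "role"), c("system", "user"))

  m5 <- build_messages(txt, "osteoporosis", "a skeletal disorder",
                       "V5_few_shot")
  expect_length(m5, 6)  # system + 2 x (example user, assistant) + user
  expect_equal(vapply(m5, `[[`, character(1), "role"),
               c("system", "user", "assistant", "user", "assistant",
                 "user"))
  expect_error(build_messages(txt, "x", "x", "V5_few_shot",
                              few_shot_examples = list()),
               "requires >= 1 example")
  expect_error(build_messages(txt, "x", "x", "V9_bogus"),
               "unknown prompt variant")
  # main prompt embeds the disease name and the serialized profile
  expect_match(m4[[2]]$content, "osteoporosis", fixed = TRUE)
  expect_match(m4[[2]]$content, txt, fixed = TRUE)
})

test_that("prompt bundles round-trip through JSONL", {
  tpl <- osteoporosis_template()
  sim <- simulate_population(tpl, simulation_params(n_persons = 60,
                                                    seed = 6))
  config <- template_keeper_config(tpl)
  cs <- concept_set("dx", data.frame(concept_id = unname(tpl$diagnosis_root),
                                     include_descendants = TRUE))
  cohort <- first_occurrence_cohort(sim$store, cs)
  profiles <- extract_profiles(sim$store, cohort, config)
  bundles <- lapply(profiles[seq_len(min(5, length(profiles)))],
                    build_prompt_bundle, config = config,
                    variant = "V5_few_shot")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_messages_jsonl(bundles, path)
  back <- read_messages_jsonl(path)
  expect_equal(length(back), length(bundles))
  for (i in seq_along(bundles)) {
    expect_identical(back[[i]]$messages, bundles[[i]]$messages)
    expect_identical(back[[i]]$person_id, bundles[[i]]$person_id)
  }
})

test_that("prompt text carries no identifier beyond the opaque person id", {
  tpl <- osteoporosis_template()
  sim <- simulate_population(tpl, simulation_params(n_persons = 40,
                                                    seed = 14))
  config <- template_keeper_config(tpl)
  cs <- concept_set("dx", data.frame(concept_id = unname(tpl$diagnosis_root),
                                     include_descendants = TRUE))
  cohort <- first_occurrence_cohort(sim$store, cs)
  profiles <- extract_profiles(sim$store, cohort, config)
  for (p in profiles) {
    b <- build_prompt_bundle(p, config)
    # no identifier fields, no calendar dates: rendering is relative-day only
    expect_no_match(b$main_prompt, "person_id|Person id", ignore.case = TRUE)
    expect_no_match(b$main_prompt, "\\d{4}-\\d{2}-\\d{2}")
  }
})
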