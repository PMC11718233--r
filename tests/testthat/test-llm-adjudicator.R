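mk_messages <- function(profile, variant = "V4_uncertainty") {
  build_messages(serialize_profile(profile), "test disease",
                 "a test definition", variant)
}

test_that("the parser handles the documented summary forms", {
  v <- parse_response("Discussion...\n\nSummary: Yes, the patient had it.")
  expect_equal(v$decision, "yes")
  expect_true(v$effective_label)

  v <- parse_response("Summary: no")
  expect_equal(v$decision, "no")
  expect_false(v$effective_label)

  # both keywords in the summary: unresolved, conservative no
  v <- parse_response("Summary: yes or no, hard to tell")
  expect_equal(v$decision, "indeterminate")
  expect_false(v$effective_label)

  # no yes/no anywhere: indeterminate, effective no
  v <- parse_response("The record is entirely unclear.")
  expect_equal(v$decision, "indeterminate")
  expect_false(v$effective_label)

  # last summary section wins
  v <- parse_response("Summary: no.\nRevised analysis...\nSummary: yes.")
  expect_equal(v$decision, "yes")

  # without a summary header only the final 200 characters are scanned
  long_prefix <- paste(rep("yes", 100), collapse = " ")
  v <- parse_response(paste0(long_prefix, "\n", strrep("filler text ", 20),
                             "the answer is no"))
  expect_equal(v$decision, "no")

  # whole words only
  expect_equal(parse_response("Summary: eyes nose")$decision,
               "indeterminate")
})

test_that("the parser is total and matches the token oracle on fuzzed text", {
  vocab <- c("yes", "no", "Yes.", "NO,", "maybe", "Summary:", "summary",
             "SUMMARY", "eyes", "nose", "yesterday", "normal", "notable",
             "patient", "disease", "\n", "\n\n", "-", ":", "(day 3)",
             "evidence", "unclear", "", "123", "yes2no")
  set.seed(424242)
  for (i in 1:1000) {
    raw <- paste(sample(vocab, sample(0:40, 1), replace = TRUE),
                 collapse = " ")
    v <- NULL
    expect_no_error(v <- parse_response(raw))
    expect_equal(v$decision, oracle_parse(raw), label = deparse(raw))
    expect_equal(v$effective_label, v$decision == "yes")
  }
})

test_that("mock rule: diagnosis alone is insufficient, support flips it", {
  dx_only <- random_profile(11)
  dx_only$items <- data.table::data.table(
    category = "preliminary_diagnosis", concept_id = 1L,
    concept_name = "Diagnosis", event_date = as.Date("2016-06-01"),
    days_from_index = 0L, domain = "condition",
    value_as_number = NA_real_, unit = NA_character_, n_occurrences = 1L)
  raw <- mock_complete(mk_messages(dx_only),
                       rule_params = list(min_support_categories = 1,
                                          differential_veto = TRUE))
  expect_equal(parse_response(raw)$decision, "no")

  supported <- dx_only
  supported$items <- rbind(supported$items, data.table::data.table(
    category = c("clinical_presentation", "treatment"),
    concept_id = 2:3, concept_name = c("Symptom", "Treatment"),
    event_date = as.Date("2016-06-01") + c(-5, 10),
    days_from_index = c(-5L, 10L), domain = c("condition", "drug"),
    value_as_number = NA_real_, unit = NA_character_, n_occurrences = 1L))
  raw <- mock_complete(mk_messages(supported),
                       rule_params = list(min_support_categories = 2,
                                          differential_veto = TRUE))
  expect_equal(parse_response(raw)$decision, "yes")
})

test_that("mock decisions match an independent rule reimplementation", {
  for (seed in 300:399) {
    p <- random_profile(seed)
    txt <- serialize_profile(p)
    raw <- mock_complete(mk_messages(p))
    expect_equal(parse_response(raw)$decision,
                 oracle_mock_decision(txt), label = paste("seed", seed))
  }
})

test_that("mock output is deterministic and empty messages are rejected", {
  p <- random_profile(55)
  msgs <- mk_messages(p)
  expect_identical(complete(mock_backend(), msgs),
                   complete(mock_backend(), msgs))
  expect_error(complete(mock_backend(), list()), "non-empty")
  # unrenderable input exercises the indeterminate path
  raw <- mock_complete(list(list(role = "user", content = "free text")))
  expect_equal(parse_response(raw)$decision, "indeterminate")
})

test_that("replay backend returns recorded transcripts byte-for-byte", {
  p <- lapply(c(61, 62), random_profile)
  msgs <- lapply(p, mk_messages)
  path <- withr::local_tempfile(fileext = ".jsonl")
  record_transcript(msgs, mock_backend(), path = path)
  rb <- replay_backend(path)
  for (m in msgs)
    expect_identical(complete(rb, m), complete(mock_backend(), m))
  expect_error(complete(rb, mk_messages(random_profile(63))),
               "no recorded response")
})

test_that("cohort adjudication is stable and resumes idempotently", {
  tpl <- osteoporosis_template()
  sim <- simulate_population(tpl, simulation_params(n_persons = 150,
                                                    seed = 19))
  config <- template_keeper_config(tpl)
  cs <- concept_set("dx", data.frame(concept_id = unname(tpl$diagnosis_root),
                                     include_descendants = TRUE))
  cohort <- first_occurrence_cohort(sim$store, cs)
  profiles <- extract_profiles(sim$store, cohort, config)

  r1 <- adjudicate_cohort(profiles, config)
  r2 <- adjudicate_cohort(profiles, config)
  expect_equal(nrow(r1), length(profiles))
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # uninterrupted run with checkpoint
  full_path <- withr::local_tempfile(fileext = ".jsonl")
  adjudicate_cohort(profiles, config, checkpoint_path = full_path)

  # interrupted run: first half pre-written, rest resumed
  part_path <- withr::local_tempfile(fileext = ".jsonl")
  half <- profiles[seq_len(floor(length(profiles) / 2))]
  adjudicate_cohort(half, config, checkpoint_path = part_path)
  resumed <- adjudicate_cohort(profiles, config,
                               checkpoint_path = part_path)
  expect_identical(readLines(part_path), readLines(full_path))
  expect_identical(as.data.frame(resumed), as.data.frame(r1))
})

test_that("pipeline sensitivity is monotone in the planted symptom signal", {
  tpl <- osteoporosis_template()
  run_sens <- function(p_sym) {
    sim <- simulate_population(tpl, simulation_params(
      n_persons = 400, prevalence = 0.3, p_symptom_given_case = p_sym,
      p_treatment_given_case = 0.5, seed = 77))
    config <- template_keeper_config(tpl)
    cs <- concept_set("dx", data.frame(
      concept_id = unname(tpl$diagnosis_root), include_descendants = TRUE))
    cohort <- first_occurrence_cohort(sim$store, cs)
    profiles <- extract_profiles(sim$store, cohort, config)
    res <- adjudicate_cohort(profiles, config)
    truth <- sim$labels[sim$labels$person_id %in% cohort$person_id]
    m <- adjudication_metrics(res, truth)
    m$sensitivity
  }
  sens <- vapply(c(0.1, 0.5, 0.9), run_sens, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("per-person backend failures are recorded and the run continues", {
  flaky <- structure(list(), class = c("flaky_backend", "llm_backend"))
  counter <- new.env(); counter$n <- 0
  registerS3method("complete", "flaky_backend",
                   function(backend, messages, params = backend_params()) {
                     counter$n <- counter$n + 1
                     if (counter$n == 2) stop("transient outage")
                     "All considered.\n\nSummary: no"
                   },
                   envir = asNamespace("keeperllm"))
  profiles <- lapply(71:73, random_profile)
  config <- keeper_config("test disease", "a test definition", list(
    keeper_category("treatment",
                    concept_set("t", data.frame(concept_id = 30L)),
                    "drug", 0, 90)))
  expect_warning(res <- adjudicate_cohort(profiles, config,
                                          backend = flaky),
                 "failed")
  expect_equal(nrow(res), 2)
  fails <- attr(res, "failures")
  expect_length(fails, 1)
  expect_equal(fails[[1]]$person_id, profiles[[2]]$person_id)
})
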