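# Profile serialization and staged prompt construction. System-prompt
# wording lives in versioned template files under inst/prompts/ so tests can
# pin bytes; parts marked "reconstructed" in the vignette were written in
# neutral phrasing where no canonical wording exists.

#' Prompt variants, in cumulative order
#'
#' Six staged prompting strategies: a bare yes/no instruction, then
#' cumulatively adding (1) discuss evidence for and against, (2) write a
#' clinical narrative, (3) a reminder that a diagnosis alone is insufficient,
#' (4) instructions for handling uncertainty, and finally (5) two few-shot
#' examples delivered as extra chat messages (system text identical to the
#' previous variant).
#'
#' @return character vector of variant ids in composition order.
#' @export
prompt_variants <- function() {
  c("V0_yes_no", "V1_discuss_evidence", "V2_write_narrative",
    "V3_diagnosis_insufficient", "V4_uncertainty", "V5_few_shot")
}

.variant_rank <- function(variant) {
  r <- match(variant, prompt_variants())
  if (is.na(r)) stop("unknown prompt variant: ", variant)
  r
}

.prompt_template <- function(name) {
  path <- system.file("prompts", paste0(name, ".txt"), package = "keeperllm")
  if (!nzchar(path)) stop("prompt template not found: ", name)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

.fill <- function(template, values) {
  for (nm in names(values))
    template <- gsub(paste0("{", nm, "}"), values[[nm]], template,
                     fixed = TRUE)
  template
}

#' Default mapping of extraction categories to display groups
#'
#' Prior-visit diagnoses (symptoms, disease history, comorbidities, risk
#' factors) are combined into a single display group; remaining categories
#' map to their own groups. Display order is the order of first appearance.
#'
#' @return named character vector: category -> display group.
#' @export
default_profile_grouping <- function() {
  c(clinical_presentation = "Diagnoses recorded prior to the visit",
    disease_history = "Diagnoses recorded prior to the visit",
    comorbidities = "Diagnoses recorded prior to the visit",
    risk_factors = "Diagnoses recorded prior to the visit",
    preliminary_diagnosis = "Diagnoses recorded at the visit",
    diagnostic_procedures = "Laboratory tests and measurements",
    differential_diagnoses = "Alternative diagnoses recorded around the visit",
    treatment = "Treatments recorded after the visit",
    follow_up_care = "Treatments recorded after the visit",
    complications = "Complications recorded after the visit")
}

#' Serialize a patient profile to deterministic prompt text
#'
#' Renders a header line (age, gender) followed by one block per display
#' group. Items appear as `concept_name (day N)` with the signed day offset
#' from index; measurements append either the recorded value or
#' "result not recorded"; repeated billing lines append an occurrence count.
#' Groups with no items render an explicit "none recorded" line so the
#' adjudicator sees absence, not omission. Identical profiles always produce
#' identical bytes.
#'
#' @param profile a `patient_profile`.
#' @param grouping named character vector category -> display group; must
#'   cover every category the profile was extracted with.
#' @return single character string.
#' @export
serialize_profile <- function(profile, grouping = default_profile_grouping()) {
  stopifnot(inherits(profile, "patient_profile"))
  uncovered <- setdiff(profile$categories, names(grouping))
  if (length(uncovered))
    stop("grouping does not cover categor(ies): ",
         paste(uncovered, collapse = ", "))
  groups <- unique(unname(grouping[profile$categories]))
  it <- profile$items
  lines <- c(sprintf("Patient: %d year old %s.", profile$age_at_index,
                     tolower(profile$gender)), "")
  for (g in groups) {
    cats <- names(grouping)[grouping == g]
    sub <- it[it$category %in% cats, ]
    lines <- c(lines, paste0(g, ":"))
    if (!nrow(sub)) {
      lines <- c(lines, "- none recorded")
    } else {
      sub <- sub[order(sub$days_from_index, sub$concept_name), ]
      for (i in seq_len(nrow(sub))) {
        entry <- sprintf("- %s (day %d", sub$concept_name[i],
                         sub$days_from_index[i])
        if (sub$domain[i] == "measurement") {
          entry <- if (!is.na(sub$value_as_number[i])) {
            paste0(entry, "; value ", format(sub$value_as_number[i]),
                   if (!is.na(sub$unit[i])) paste0(" ", sub$unit[i]) else "")
          } else paste0(entry, "; result not recorded")
        }
        if (sub$n_occurrences[i] > 1L)
          entry <- paste0(entry, "; recorded ", sub$n_occurrences[i],
                          " times")
        lines <- c(lines, paste0(entry, ")"))
      }
    }
    lines <- c(lines, "")
  }
  paste(lines[-length(lines)], collapse = "\n")
}

#' Compose the staged system prompt for a variant
#'
#' The base instruction (binary yes/no with a mandatory final "Summary:"
#' section) is always present; parts 1-4 are appended cumulatively per
#' variant. The few-shot variant reuses the full four-part text — its
#' examples travel as extra chat messages, not system text.
#'
#' @param variant one of [prompt_variants()].
#' @param disease_name disease display name, substituted into the base text.
#' @return single character string.
#' @export
build_system_prompt <- function(variant, disease_name) {
  rank <- .variant_rank(variant)
  parts <- c("system_part1_evidence", "system_part2_narrative",
             "system_part3_diagnosis_insufficient", "system_part4_uncertainty")
  n_parts <- min(rank - 1L, 4L)
  texts <- c(.fill(.prompt_template("system_base"),
                   list(disease_name = disease_name)),
             vapply(parts[seq_len(n_parts)], .prompt_template, character(1)))
  paste(texts, collapse = "\n\n")
}

#' Build the main (user) prompt around a serialized profile
#'
#' @param profile_text output of [serialize_profile()].
#' @param disease_name disease display name.
#' @param conceptual_definition one-sentence clinical case definition.
#' @return single character string.
#' @export
build_main_prompt <- function(profile_text, disease_name,
                              conceptual_definition) {
  .fill(.prompt_template("main_prompt"),
        list(profile = profile_text, disease_name = disease_name,
             conceptual_definition = conceptual_definition))
}

#' Synthetic few-shot examples for the few-shot variant
#'
#' Two worked examples — one clear positive (diagnosis with supporting
#' symptoms, workup and treatment) and one clear negative (isolated
#' diagnosis code only) — rendered in the same profile serialization as real
#' prompts, each paired with an ideal response ending in a Summary section.
#' Entirely synthetic; configurable per disease by supplying your own
#' examples to [build_messages()].
#'
#' @param disease_name disease display name.
#' @param conceptual_definition case definition used in the example prompts.
#' @return list of `list(main_prompt, ideal_response)` pairs.
#' @export
default_few_shot_examples <- function(disease_name,
                                      conceptual_definition = disease_name) {
  mk_profile <- function(age, gender, items) {
    structure(list(person_id = 0L, index_date = as.Date("2000-01-01"),
                   age_at_index = age, gender = gender,
                   disease_name = disease_name,
                   categories = names(default_profile_grouping()),
                   items = items),
              class = "patient_profile")
  }
  item <- function(category, name, day, domain = "condition",
                   value = NA_real_) {
    data.table::data.table(category = category, concept_id = 0L,
                           concept_name = name,
                           event_date = as.Date("2000-01-01") + day,
                           days_from_index = as.integer(day), domain = domain,
                           value_as_number = value, unit = NA_character_,
                           n_occurrences = 1L)
  }
  pos <- mk_profile(67L, "FEMALE", data.table::rbindlist(list(
    item("clinical_presentation", "Characteristic symptom", -14L),
    item("preliminary_diagnosis", paste("Diagnosis of", disease_name), 0L),
    item("diagnostic_procedures", "Confirmatory laboratory test", 2L,
         "measurement", 42),
    item("treatment", "Disease-specific treatment", 10L, "drug"))))
  neg <- mk_profile(45L, "MALE",
                    item("preliminary_diagnosis",
                         paste("Diagnosis of", disease_name), 0L))
  pos_resp <- paste(
    "Evidence in favor: a characteristic symptom shortly before the index",
    "date, a confirmatory laboratory result, and a disease-specific",
    "treatment started after the diagnosis. Evidence against: none of",
    "note. Narrative: the patient presented with typical symptoms, was",
    "diagnosed, confirmed by testing, and started on treatment.",
    "\n\nSummary: yes")
  neg_resp <- paste(
    "Evidence in favor: a single recorded diagnosis code. Evidence",
    "against: no symptoms, no laboratory workup, no treatment, and no",
    "follow-up of any kind. Narrative: an isolated diagnosis code without",
    "any corroborating care is most consistent with a rule-out or coding",
    "artifact rather than true disease.", "\n\nSummary: no")
  lapply(list(list(p = pos, r = pos_resp), list(p = neg, r = neg_resp)),
         function(e) list(
           main_prompt = build_main_prompt(serialize_profile(e$p),
                                           disease_name,
                                           conceptual_definition),
           ideal_response = e$r))
}

#' Assemble the ordered chat message list for one patient
#'
#' Message order is: system prompt, then for the few-shot variant each
#' example's main prompt (user) and ideal response (assistant), then the
#' patient's main prompt (user).
#'
#' @param profile_text serialized profile text.
#' @param disease_name disease display name.
#' @param conceptual_definition clinical case definition.
#' @param variant one of [prompt_variants()].
#' @param few_shot_examples list of `list(main_prompt, ideal_response)`;
#'   required (and defaulted to [default_few_shot_examples()]) for the
#'   few-shot variant, ignored otherwise.
#' @return list of `list(role, content)` messages.
#' @export
build_messages <- function(profile_text, disease_name, conceptual_definition,
                           variant = "V4_uncertainty",
                           few_shot_examples = NULL) {
  rank <- .variant_rank(variant)
  msgs <- list(list(role = "system",
                    content = build_system_prompt(variant, disease_name)))
  if (variant == "V5_few_shot") {
    if (is.null(few_shot_examples))
      few_shot_examples <- default_few_shot_examples(disease_name,
                                                     conceptual_definition)
    if (!length(few_shot_examples))
      stop("the few-shot variant requires >= 1 example")
    for (ex in few_shot_examples) {
      msgs <- c(msgs, list(list(role = "user", content = ex$main_prompt),
                           list(role = "assistant",
                                content = ex$ideal_response)))
    }
  }
  c(msgs, list(list(role = "user",
                    content = build_main_prompt(profile_text, disease_name,
                                                conceptual_definition))))
}

#' Build a full prompt bundle for one profile
#'
#' @param profile a `patient_profile`.
#' @param config the [keeper_config()] used for extraction (supplies the
#'   disease name and conceptual definition).
#' @param variant one of [prompt_variants()].
#' @param grouping category -> display-group mapping.
#' @param few_shot_examples see [build_messages()].
#' @return object of class `prompt_bundle` with `system_prompt`,
#'   `main_prompt`, `messages`, `variant`, `disease_name`, `person_id`.
#' @export
build_prompt_bundle <- function(profile, config, variant = "V4_uncertainty",
                                grouping = default_profile_grouping(),
                                few_shot_examples = NULL) {
  stopifnot(inherits(config, "keeper_config"))
  profile_text <- serialize_profile(profile, grouping)
  msgs <- build_messages(profile_text, config$disease_name,
                         config$conceptual_definition, variant,
                         few_shot_examples)
  structure(list(system_prompt = msgs[[1L]]$content,
                 main_prompt = msgs[[length(msgs)]]$content,
                 messages = msgs,
                 variant = variant,
                 disease_name = config$disease_name,
                 person_id = profile$person_id),
            class = "prompt_bundle")
}

#' Write / read message bundles as JSONL
#'
#' One line per bundle: `{person_id, variant, messages: [{role, content}]}`.
#'
#' @param bundles list of `prompt_bundle` objects.
#' @param path JSONL path.
#' @return path (write) or list of bundles (read; messages only).
#' @export
write_messages_jsonl <- function(bundles, path) {
  recs <- lapply(bundles, function(b) list(
    person_id = b$person_id, variant = b$variant,
    disease_name = b$disease_name,
    messages = lapply(b$messages, function(m)
      list(role = m$role, content = m$content))))
  write_jsonl(recs, path)
}

#' @rdname write_messages_jsonl
#' @export
read_messages_jsonl <- function(path) {
  lapply(read_jsonl(path), function(r) {
    msgs <- if (is.data.frame(r$messages)) {
      lapply(seq_len(nrow(r$messages)), function(i)
        list(role = r$messages$role[i], content = r$messages$content[i]))
    } else lapply(r$messages, function(m)
      list(role = m$role, content = m$content))
    structure(list(system_prompt = msgs[[1L]]$content,
                   main_prompt = msgs[[length(msgs)]]$content,
                   messages = msgs, variant = r$variant,
                   disease_name = r$disease_name,
                   person_id = as.integer(r$person_id)),
              class = "prompt_bundle")
  })
}
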