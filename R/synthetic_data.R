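# Seeded synthetic OMOP-shaped populations with planted case structure.
#
# Patient-level claims/EHR sources cannot be shared, so every downstream
# stage (cohorts, profile extraction, prompting, adjudication, evaluation)
# is exercised against generated stores with known truth labels.

#' Describe a disease for the synthetic generator
#'
#' A disease template names the concepts the generator plants: a diagnosis
#' root with >= 2 descendant codes (conditions), symptoms, comorbidities
#' (conditions), treatments (drugs), differential diagnoses (conditions) with
#' paired bait treatments, laboratory tests (measurements), and unrelated
#' background concepts. Concept vectors are named integers
#' (`c("Back pain" = 2002L, ...)`); all ids must be disjoint.
#'
#' @param disease_name display name, used in prompts.
#' @param conceptual_definition one-sentence clinical definition, embedded in
#'   the main prompt.
#' @param diagnosis_root named length-1 integer: the standard concept whose
#'   descendants define the phenotype entry codes.
#' @param diagnosis_descendants named integer vector (>= 2) of descendant
#'   diagnosis codes.
#' @param symptoms,comorbidities,treatments,differentials,differential_treatments,labs
#'   named integer vectors of planted concepts (see Details).
#' @param background data.frame `(concept_id, concept_name, domain)` of
#'   unrelated filler concepts drawn for background noise.
#' @return object of class `disease_template`.
#' @export
disease_template <- function(disease_name, conceptual_definition,
                             diagnosis_root, diagnosis_descendants,
                             symptoms, comorbidities, treatments,
                             differentials, differential_treatments,
                             labs, background) {
  named_int <- function(x, what, min_len = 1) {
    if (length(x) < min_len || is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " must be a named integer vector of length >= ", min_len)
    stats::setNames(as.integer(x), names(x))
  }
  tpl <- list(
    disease_name = as.character(disease_name),
    conceptual_definition = as.character(conceptual_definition),
    diagnosis_root = named_int(diagnosis_root, "diagnosis_root"),
    diagnosis_descendants = named_int(diagnosis_descendants,
                                      "diagnosis_descendants", 2),
    symptoms = named_int(symptoms, "symptoms"),
    comorbidities = named_int(comorbidities, "comorbidities"),
    treatments = named_int(treatments, "treatments"),
    differentials = named_int(differentials, "differentials"),
    differential_treatments = named_int(differential_treatments,
                                        "differential_treatments"),
    labs = named_int(labs, "labs"),
    background = as.data.frame(background)
  )
  ids <- c(tpl$diagnosis_root, tpl$diagnosis_descendants, tpl$symptoms,
           tpl$comorbidities, tpl$treatments, tpl$differentials,
           tpl$differential_treatments, tpl$labs, tpl$background$concept_id)
  if (anyDuplicated(ids))
    stop("concept lists in a disease template must be disjoint; duplicated ",
         "id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(tpl, class = "disease_template")
}

#' Illustrative osteoporosis disease template
#'
#' A toy-scale stand-in for a real osteoporosis vocabulary: one standard
#' diagnosis concept with a few descendant codes (real vocabularies map
#' hundreds of ICD-10 codes under such a concept), plus symptoms,
#' comorbidities, bisphosphonate treatments, differential diagnoses and
#' laboratory tests. Synthetic and illustrative, not a clinical concept set.
#'
#' @return a [disease_template()].
#' @export
osteoporosis_template <- function() {
  disease_template(
    disease_name = "osteoporosis",
    conceptual_definition = paste(
      "a skeletal disorder characterized by decreased bone density and",
      "strength, leading to fragile bones and an increased risk of fractures"),
    diagnosis_root = c("Osteoporosis" = 1000L),
    diagnosis_descendants = c("Postmenopausal osteoporosis" = 1001L,
                              "Osteoporosis, unspecified" = 1002L,
                              "Senile osteoporosis" = 1003L),
    symptoms = c("Joint pain of pelvic region" = 2001L,
                 "Back pain" = 2002L,
                 "Loss of height" = 2003L),
    comorbidities = c("Fracture of bone" = 2101L,
                      "Vitamin D deficiency" = 2102L),
    treatments = c("Zoledronic acid" = 3001L,
                   "Alendronate" = 3002L),
    differentials = c("Osteomalacia" = 2201L,
                      "Malignant neoplastic disease" = 2202L),
    differential_treatments = c("Ergocalciferol" = 3101L,
                                "Chemotherapy regimen" = 3102L),
    labs = c("Bone density scan" = 4001L,
             "Serum calcium measurement" = 4002L),
    background = data.frame(
      concept_id = 9001:9010,
      concept_name = c("Acute upper respiratory infection", "Hypertension",
                       "Ibuprofen", "Amoxicillin", "Hemoglobin measurement",
                       "Lipid panel", "Screening colonoscopy",
                       "Influenza vaccination", "Outpatient visit",
                       "Tobacco use"),
      domain = c("condition", "condition", "drug", "drug", "measurement",
                 "measurement", "procedure", "procedure", "visit",
                 "observation")))
}

#' Illustrative rheumatoid arthritis disease template
#'
#' Companion template for a second disease, used in the high-sensitivity
#' cohort demonstrations. Synthetic and illustrative.
#'
#' @return a [disease_template()].
#' @export
ra_template <- function() {
  disease_template(
    disease_name = "rheumatoid arthritis",
    conceptual_definition = paste(
      "a chronic autoimmune inflammatory disease primarily affecting",
      "synovial joints, presenting with symmetric polyarthritis, morning",
      "stiffness, and elevated inflammatory markers"),
    diagnosis_root = c("Rheumatoid arthritis" = 1500L),
    diagnosis_descendants = c("Seropositive rheumatoid arthritis" = 1501L,
                              "Seronegative rheumatoid arthritis" = 1502L,
                              "Rheumatoid arthritis of hand" = 1503L),
    symptoms = c("Joint pain" = 2501L,
                 "Joint swelling" = 2502L,
                 "Morning stiffness" = 2503L),
    comorbidities = c("Sjogren's syndrome" = 2601L,
                      "Anemia of chronic disease" = 2602L),
    treatments = c("Methotrexate" = 3501L,
                   "Adalimumab" = 3502L),
    differentials = c("Osteoarthritis" = 2701L,
                      "Systemic lupus erythematosus" = 2702L),
    differential_treatments = c("Acetaminophen" = 3601L,
                                "Hydroxychloroquine" = 3602L),
    labs = c("Rheumatoid factor measurement" = 4501L,
             "C-reactive protein measurement" = 4502L),
    background = data.frame(
      concept_id = 9101:9110,
      concept_name = c("Acute bronchitis", "Type 2 diabetes mellitus",
                       "Lisinopril", "Atorvastatin", "Basic metabolic panel",
                       "Urinalysis", "Chest radiograph",
                       "Physical therapy evaluation", "Inpatient visit",
                       "Body mass index finding"),
      domain = c("condition", "condition", "drug", "drug", "measurement",
                 "measurement", "procedure", "procedure", "visit",
                 "observation")))
}

#' Simulation parameters for the synthetic population
#'
#' Probabilities condition on planted true-case status; `background_event_rate`
#' is the Poisson mean of unrelated events per person; about
#' `lab_result_recording_rate` of laboratory orders carry a numeric result
#' (claims sources typically record results for only a minority of orders).
#'
#' @param n_persons population size.
#' @param prevalence probability a person is a planted true case.
#' @param p_symptom_given_case per-symptom (and per-lab-order) planting
#'   probability for cases.
#' @param p_treatment_given_case per-treatment planting probability for cases.
#' @param p_comorbidity_given_case per-comorbidity planting probability.
#' @param p_spurious_diagnosis_given_noncase probability a non-case receives
#'   one isolated diagnosis code with no supporting evidence.
#' @param p_differential_given_noncase probability a non-case receives a
#'   differential diagnosis plus its paired treatment (false-positive bait).
#' @param background_event_rate mean unrelated events per person.
#' @param lab_result_recording_rate fraction of measurement events carrying a
#'   numeric value.
#' @param seed global integer seed; per-person substreams are derived from it.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_persons = 2000,
                              prevalence = 0.1,
                              p_symptom_given_case = 0.8,
                              p_treatment_given_case = 0.7,
                              p_comorbidity_given_case = 0.5,
                              p_spurious_diagnosis_given_noncase = 0.05,
                              p_differential_given_noncase = 0.2,
                              background_event_rate = 5,
                              lab_result_recording_rate = 0.3,
                              seed = 1L) {
  p <- list(n_persons = as.integer(n_persons),
            prevalence = prevalence,
            p_symptom_given_case = p_symptom_given_case,
            p_treatment_given_case = p_treatment_given_case,
            p_comorbidity_given_case = p_comorbidity_given_case,
            p_spurious_diagnosis_given_noncase =
              p_spurious_diagnosis_given_noncase,
            p_differential_given_noncase = p_differential_given_noncase,
            background_event_rate = background_event_rate,
            lab_result_recording_rate = lab_result_recording_rate,
            seed = as.integer(seed))
  probs <- unlist(p[c("prevalence", "p_symptom_given_case",
                      "p_treatment_given_case", "p_comorbidity_given_case",
                      "p_spurious_diagnosis_given_noncase",
                      "p_differential_given_noncase",
                      "lab_result_recording_rate")])
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (p$n_persons < 1) stop("n_persons must be >= 1")
  if (p$background_event_rate < 0)
    stop("background_event_rate must be >= 0")
  structure(p, class = "simulation_params")
}

#' Build the toy vocabulary for a disease template
#'
#' Emits the concept table and the reflexive-transitive ancestry closure:
#' reflexive rows for every concept plus root -> descendant rows for the
#' diagnosis hierarchy (one root, its descendant codes).
#'
#' @param template a [disease_template()].
#' @return list with `concept` and `concept_ancestor` data.tables.
#' @export
build_toy_vocabulary <- function(template) {
  stopifnot(inherits(template, "disease_template"))
  seg <- function(x, domain) data.table::data.table(
    concept_id = unname(x), concept_name = names(x), domain = domain)
  concept <- data.table::rbindlist(list(
    seg(template$diagnosis_root, "condition"),
    seg(template$diagnosis_descendants, "condition"),
    seg(template$symptoms, "condition"),
    seg(template$comorbidities, "condition"),
    seg(template$differentials, "condition"),
    seg(template$treatments, "drug"),
    seg(template$differential_treatments, "drug"),
    seg(template$labs, "measurement"),
    data.table::as.data.table(template$background)))
  if (anyDuplicated(concept$concept_id))
    stop("duplicate concept ids in template vocabulary")
  ca <- data.table::data.table(
    ancestor_concept_id = c(concept$concept_id,
                            rep(unname(template$diagnosis_root),
                                length(template$diagnosis_descendants))),
    descendant_concept_id = c(concept$concept_id,
                              unname(template$diagnosis_descendants)))
  data.table::setorder(ca, ancestor_concept_id, descendant_concept_id)
  list(concept = concept, concept_ancestor = ca)
}

# Window constants for planting, aligned with the default extraction windows
# so the planted signal falls where extraction looks: symptoms 1..30 days
# before index, lab orders 0..30 before, comorbidities 31..1800 before,
# treatments 0..90 after.
.plant_windows <- list(symptom = c(1L, 30L), lab = c(0L, 30L),
                       comorbidity = c(31L, 1800L), treatment = c(0L, 90L))

#' Simulate a population with planted case structure
#'
#' Each person is a planted true case with probability `prevalence`. Cases
#' receive one descendant diagnosis code on their true index date, each
#' symptom and laboratory order with probability `p_symptom_given_case`
#' shortly before/at index, each comorbidity with probability
#' `p_comorbidity_given_case` well before index, and each treatment with
#' probability `p_treatment_given_case` after index. Non-cases may receive an
#' isolated spurious diagnosis, or a differential diagnosis plus its paired
#' treatment. Everyone accrues Poisson background events from unrelated
#' concepts. Measurement events carry a numeric result with probability
#' `lab_result_recording_rate`.
#'
#' Reproducibility: person `i` draws from a substream derived from
#' `(params$seed, i)`, so results are identical across runs and unchanged for
#' existing persons when `n_persons` grows.
#'
#' @param template a [disease_template()].
#' @param params a [simulation_params()].
#' @return list with `store` (a [cdm_store()]) and `labels` (data.table
#'   `person_id, true_case, true_index_date`).
#' @export
simulate_population <- function(template, params) {
  stopifnot(inherits(template, "disease_template"),
            inherits(params, "simulation_params"))
  vocab <- build_toy_vocabulary(template)
  dom_of <- stats::setNames(vocab$concept$domain, vocab$concept$concept_id)
  date0 <- as.Date("2015-01-01")
  span <- as.integer(as.Date("2019-12-31") - date0)  # random index window
  bg_ids <- template$background$concept_id
  n <- params$n_persons

  per <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derived_seed(params$seed, i))
    yob <- sample(1930:1990, 1L)
    gender <- sample(c("FEMALE", "MALE"), 1L)
    is_case <- runif(1) < params$prevalence
    concept <- integer(0); day <- integer(0)
    index_day <- NA_integer_
    if (is_case) {
      index_day <- sample.int(span + 1L, 1L) - 1L
      concept <- c(concept, sample(unname(template$diagnosis_descendants), 1L))
      day <- c(day, index_day)
      plant <- function(ids, p, win, before) {
        keep <- ids[runif(length(ids)) < p]
        if (!length(keep)) return(NULL)
        off <- sample(win[1]:win[2], length(keep), replace = TRUE)
        list(id = unname(keep),
             day = if (before) index_day - off else index_day + off)
      }
      for (pl in list(
        plant(template$symptoms, params$p_symptom_given_case,
              .plant_windows$symptom, before = TRUE),
        plant(template$labs, params$p_symptom_given_case,
              .plant_windows$lab, before = TRUE),
        plant(template$comorbidities, params$p_comorbidity_given_case,
              .plant_windows$comorbidity, before = TRUE),
        plant(template$treatments, params$p_treatment_given_case,
              .plant_windows$treatment, before = FALSE))) {
        if (!is.null(pl)) { concept <- c(concept, pl$id); day <- c(day, pl$day) }
      }
    } else {
      if (runif(1) < params$p_spurious_diagnosis_given_noncase) {
        concept <- c(concept,
                     sample(unname(template$diagnosis_descendants), 1L))
        day <- c(day, sample.int(span + 1L, 1L) - 1L)
      }
      if (runif(1) < params$p_differential_given_noncase) {
        j <- sample.int(length(template$differentials), 1L)
        d0 <- sample.int(span + 1L, 1L) - 1L
        tr <- template$differential_treatments[
          ((j - 1L) %% length(template$differential_treatments)) + 1L]
        concept <- c(concept, unname(template$differentials[j]), unname(tr))
        day <- c(day, d0, d0 + sample(0:90, 1L))
      }
    }
    n_bg <- rpois(1L, params$background_event_rate)
    if (n_bg > 0) {
      concept <- c(concept, sample(bg_ids, n_bg, replace = TRUE))
      day <- c(day, sample.int(span + 1L, n_bg, replace = TRUE) - 1L)
    }
    value <- rep(NA_real_, length(concept))
    is_meas <- dom_of[as.character(concept)] == "measurement"
    if (any(is_meas)) {
      rec <- is_meas & runif(length(concept)) < params$lab_result_recording_rate
      value[rec] <- round(runif(sum(rec), 10, 200), 1)
    }
    per[[i]] <- list(yob = yob, gender = gender, case = is_case,
                     index_day = index_day, concept = concept, day = day,
                     value = value)
  }

  lens <- vapply(per, function(x) length(x$concept), integer(1))
  concept_all <- unlist(lapply(per, `[[`, "concept"), use.names = FALSE)
  event <- data.table::data.table(
    person_id = rep(seq_len(n), lens),
    concept_id = concept_all,
    event_date = date0 + unlist(lapply(per, `[[`, "day"), use.names = FALSE),
    domain = unname(dom_of[as.character(concept_all)]),
    value_as_number = unlist(lapply(per, `[[`, "value"), use.names = FALSE),
    unit = NA_character_)
  event[!is.na(value_as_number), unit := "unit"]
  person <- data.table::data.table(
    person_id = seq_len(n),
    year_of_birth = vapply(per, `[[`, integer(1), "yob"),
    gender = vapply(per, `[[`, character(1), "gender"))
  labels <- data.table::data.table(
    person_id = seq_len(n),
    true_case = vapply(per, `[[`, logical(1), "case"),
    true_index_date = date0 +
      vapply(per, `[[`, integer(1), "index_day"))
  store <- cdm_store(person = person, event = event,
                     concept = vocab$concept,
                     concept_ancestor = vocab$concept_ancestor)
  list(store = store, labels = labels)
}

#' Summarize truth or silver labels
#'
#' @param labels data.frame with logical column `true_case` (or `label`).
#' @param digits decimals for the percentage (half-away-from-zero).
#' @return list `(n_persons, n_cases, case_fraction, case_fraction_pct)`.
#' @export
truth_summary <- function(labels, digits = 1) {
  labels <- as.data.frame(labels)
  if (!nrow(labels)) stop("labels must be non-empty")
  col <- if ("true_case" %in% names(labels)) "true_case" else "label"
  if (!col %in% names(labels))
    stop("labels must have a 'true_case' or 'label' column")
  n <- nrow(labels)
  k <- sum(labels[[col]])
  list(n_persons = n, n_cases = k, case_fraction = k / n,
       case_fraction_pct = round_half_up(100 * k / n, digits))
}

#' Write / read truth labels as CSV
#'
#' @param labels data.table `(person_id, true_case, true_index_date)`.
#' @param path file path.
#' @return the path (write) or the labels (read).
#' @export
write_truth_labels <- function(labels, path) {
  out <- data.table::as.data.table(labels)[order(person_id)]
  data.table::fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_truth_labels
#' @export
read_truth_labels <- function(path) {
  x <- data.table::fread(path, showProgress = FALSE)
  x[, person_id := as.integer(person_id)]
  x[, true_case := as.logical(true_case)]
  x[, true_index_date := as_iso_date(true_index_date)]
  x[]
}
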