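# Backend contract for chat-completion adjudication, a deterministic mock
# backend for offline runs, a recorded-replay backend for regression tests,
# response parsing into binary verdicts, and cohort-scale adjudication with
# JSONL checkpoint/resume.

#' Backend call parameters
#'
#' Deterministic adjudication uses temperature 0 (the default); the
#' remaining fields describe the hosted model for HTTP backends and are
#' carried into result metadata.
#'
#' @param temperature sampling temperature, `>= 0`; default 0.
#' @param max_output_tokens response length cap passed to HTTP backends.
#' @param model_name model identifier recorded with results.
#' @param endpoint opaque service locator for HTTP backends.
#' @return object of class `backend_params`.
#' @export
backend_params <- function(temperature = 0, max_output_tokens = 1024L,
                           model_name = "mock", endpoint = NULL) {
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(temperature = temperature,
                 max_output_tokens = as.integer(max_output_tokens),
                 model_name = model_name, endpoint = endpoint),
            class = "backend_params")
}

#' Deterministic rule-based mock backend
#'
#' Re-reads the serialized profile out of the main prompt and applies a
#' fixed clinical-shaped rule: answer "yes" iff the number of non-empty
#' supporting display groups (prior diagnoses incl. symptoms/history,
#' laboratory tests, treatments, complications) is at least
#' `min_support_categories`, and — when `differential_veto` is set — the
#' alternative-diagnosis items do not outnumber the supporting items. A
#' bare diagnosis code with no support is always "no". The response carries
#' evidence-for, evidence-against and narrative sections and ends with a
#' "Summary: yes/no" section in the format the parser expects.
#'
#' @param min_support_categories minimum count of non-empty supporting
#'   groups for a "yes".
#' @param differential_veto veto a "yes" when alternative-diagnosis items
#'   outnumber supporting items.
#' @return object of class `c("mock_backend", "llm_backend")`.
#' @export
mock_backend <- function(min_support_categories = 2L,
                         differential_veto = TRUE) {
  structure(list(min_support_categories = as.integer(min_support_categories),
                 differential_veto = isTRUE(differential_veto),
                 supporting_groups = c(
                   "Diagnoses recorded prior to the visit",
                   "Laboratory tests and measurements",
                   "Treatments recorded after the visit",
                   "Complications recorded after the visit"),
                 differential_group =
                   "Alternative diagnoses recorded around the visit"),
            class = c("mock_backend", "llm_backend"))
}

#' Recorded-replay backend
#'
#' Replays stored transcripts: each record pairs the full concatenated
#' message text with the recorded response, returned byte-for-byte. Use
#' [record_transcript()] to capture transcripts from any live backend.
#'
#' @param transcript path to a transcript JSONL (records
#'   `{key, response}`) or a list of such records.
#' @return object of class `c("replay_backend", "llm_backend")`.
#' @export
replay_backend <- function(transcript) {
  recs <- if (is.character(transcript)) read_jsonl(transcript) else transcript
  map <- new.env(parent = emptyenv())
  for (r in recs) assign(r$key, r$response, envir = map)
  structure(list(map = map, n = length(recs)),
            class = c("replay_backend", "llm_backend"))
}

# Canonical replay key: role-tagged concatenation of all messages.
message_key <- function(messages) {
  paste(vapply(messages, function(m) paste0(m$role, "\x1f", m$content),
               character(1)), collapse = "\x1e")
}

#' Record a transcript for later replay
#'
#' @param messages_list list of message lists.
#' @param backend any backend to query.
#' @param params [backend_params()].
#' @param path optional JSONL output path.
#' @return list of `{key, response}` records (invisibly written to `path`).
#' @export
record_transcript <- function(messages_list, backend,
                              params = backend_params(), path = NULL) {
  recs <- lapply(messages_list, function(m)
    list(key = message_key(m), response = complete(backend, m, params)))
  if (!is.null(path)) write_jsonl(recs, path)
  invisible(recs)
}

#' HTTP chat-completions backend
#'
#' Speaks one neutral chat-completions request shape
#' (`{model, messages, temperature, max_tokens}`) via the system `curl`
#' binary; provider specifics are limited to the endpoint URL and an API
#' key referenced by environment-variable name (never stored). Transient
#' failures are retried with bounded exponential backoff.
#'
#' @param endpoint full URL of the chat-completions route.
#' @param api_key_env name of the environment variable holding the key.
#' @param max_retries retry budget for transient failures.
#' @return object of class `c("http_backend", "llm_backend")`.
#' @export
http_backend <- function(endpoint, api_key_env = "LLM_API_KEY",
                         max_retries = 3L) {
  structure(list(endpoint = endpoint, api_key_env = api_key_env,
                 max_retries = as.integer(max_retries)),
            class = c("http_backend", "llm_backend"))
}

#' Request one completion from a backend
#'
#' Stateless per call; the mock and replay backends are fully
#' deterministic, matching temperature-0 usage.
#'
#' @param backend an `llm_backend`.
#' @param messages non-empty list of `list(role, content)` messages.
#' @param params [backend_params()].
#' @return raw response text.
#' @export
complete <- function(backend, messages, params = backend_params()) {
  if (!length(messages)) stop("messages must be non-empty")
  UseMethod("complete")
}

#' @export
complete.mock_backend <- function(backend, messages,
                                  params = backend_params()) {
  mock_complete(messages,
                rule_params = list(
                  min_support_categories = backend$min_support_categories,
                  differential_veto = backend$differential_veto),
                supporting_groups = backend$supporting_groups,
                differential_group = backend$differential_group)
}

#' @export
complete.replay_backend <- function(backend, messages,
                                    params = backend_params()) {
  key <- message_key(messages)
  if (!exists(key, envir = backend$map, inherits = FALSE))
    stop("replay backend has no recorded response for this message list")
  get(key, envir = backend$map, inherits = FALSE)
}

#' @export
complete.http_backend <- function(backend, messages,
                                  params = backend_params()) {
  body <- jsonlite::toJSON(list(
    model = params$model_name,
    messages = lapply(messages, function(m)
      list(role = m$role, content = m$content)),
    temperature = params$temperature,
    max_tokens = params$max_output_tokens), auto_unbox = TRUE)
  key <- Sys.getenv(backend$api_key_env, "")
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    tmp <- tempfile(fileext = ".json")
    writeLines(as.character(body), tmp)
    out <- suppressWarnings(system2(
      "curl", c("-sS", "--fail-with-body", "-X", "POST",
                "-H", "Content-Type: application/json",
                if (nzchar(key)) c("-H", paste0("Authorization: Bearer ",
                                                key)),
                "--data", paste0("@", tmp), shQuote(backend$endpoint)),
      stdout = TRUE, stderr = TRUE))
    unlink(tmp)
    status <- attr(out, "status") %||% 0L
    if (status == 0L) {
      parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                                   simplifyVector = FALSE)
      return(parsed$choices[[1L]]$message$content)
    }
    if (attempt > backend$max_retries)
      stop("http backend failed after ", attempt, " attempt(s): ",
           paste(out, collapse = " "))
    Sys.sleep(min(2^attempt, 30))
  }
}

# ---- mock rule ----

# Parses the serialized profile back out of free prompt text: display-group
# headers are lines ending ":" (excluding the trailing question), items are
# "- " lines; "- none recorded" marks an empty group.
parse_profile_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  blocks <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^Question:", ln)) break
    if (grepl(":$", ln)) {
      current <- sub(":$", "", ln)
      blocks[[current]] <- character(0)
    } else if (!is.null(current) && grepl("^- ", ln)) {
      item <- sub("^- ", "", ln)
      if (item != "none recorded")
        blocks[[current]] <- c(blocks[[current]], item)
    }
  }
  blocks
}

#' Deterministic mock adjudication of one message list
#'
#' See [mock_backend()] for the decision rule. If no profile rendering can
#' be found in the main message, the response intentionally carries no
#' Summary section, exercising the parser's indeterminate path.
#'
#' @param messages message list whose final user message embeds a profile
#'   in the canonical rendering.
#' @param rule_params list with `min_support_categories` and
#'   `differential_veto`.
#' @param supporting_groups,differential_group display-group names the rule
#'   counts.
#' @return raw response text.
#' @export
mock_complete <- function(messages,
                          rule_params = list(min_support_categories = 2L,
                                             differential_veto = TRUE),
                          supporting_groups = mock_backend()$supporting_groups,
                          differential_group =
                            mock_backend()$differential_group) {
  if (!length(messages)) stop("messages must be non-empty")
  main <- messages[[length(messages)]]$content
  blocks <- parse_profile_blocks(main)
  if (!length(blocks))
    return(paste(
      "The provided text does not contain a structured patient profile in",
      "the expected rendering, so an adjudication could not be made."))
  support <- blocks[intersect(supporting_groups, names(blocks))]
  n_support_groups <- sum(vapply(support, length, integer(1)) > 0L)
  n_support_items <- sum(vapply(support, length, integer(1)))
  n_diff_items <- length(blocks[[differential_group]])
  decision <- n_support_groups >= rule_params$min_support_categories
  vetoed <- FALSE
  if (decision && isTRUE(rule_params$differential_veto) &&
      n_diff_items > n_support_items) {
    decision <- FALSE
    vetoed <- TRUE
  }
  nonempty <- names(support)[vapply(support, length, integer(1)) > 0L]
  paste0(
    "Evidence in favor: ", n_support_groups,
    " supporting group(s) with findings",
    if (length(nonempty)) paste0(" (", paste(nonempty, collapse = "; "), ")"),
    ", ", n_support_items, " supporting item(s) in total.\n",
    "Evidence against: ", n_diff_items,
    " alternative-diagnosis item(s) recorded",
    if (vetoed) ", which outweigh the supporting evidence", ".\n",
    "Clinical narrative: the recorded items ",
    if (decision) "form a coherent course of presentation, diagnosis and management consistent with the disease."
    else "do not add up to a corroborated course of the disease; a diagnosis code alone, or a better alternative explanation, accounts for the record.",
    "\n\nSummary: ", if (decision) "yes" else "no")
}

# ---- response parsing ----

#' Parse a backend response into a binary verdict
#'
#' Locates the last section whose header matches `summary`
#' (case-insensitive); within it scans for whole-word "yes"/"no"
#' (case-insensitive). Exactly one keyword found gives that decision; both
#' or neither give `indeterminate`, which carries an effective label of
#' "no" — the conservative reading of an unresolved adjudication. Without
#' any summary header, the final 200 characters are scanned under the same
#' rule. Total: never errors on arbitrary text.
#'
#' @param raw response text (anything coercible to character).
#' @return object of class `verdict`: `decision`
#'   (`"yes"`/`"no"`/`"indeterminate"`), `effective_label` (logical),
#'   `summary_text`, `raw_response`.
#' @export
parse_response <- function(raw) {
  raw <- paste(as.character(raw %||% ""), collapse = "\n")
  if (is.na(raw)) raw <- ""
  m <- gregexpr("\\bsummary\\b", raw, ignore.case = TRUE, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    summary_text <- substring(raw, m[length(m)])
  } else {
    summary_text <- substring(raw, max(1L, nchar(raw) - 199L))
  }
  has_yes <- grepl("\\byes\\b", summary_text, ignore.case = TRUE, perl = TRUE)
  has_no <- grepl("\\bno\\b", summary_text, ignore.case = TRUE, perl = TRUE)
  decision <- if (has_yes && !has_no) "yes"
  else if (has_no && !has_yes) "no"
  else "indeterminate"
  structure(list(decision = decision,
                 effective_label = identical(decision, "yes"),
                 summary_text = summary_text,
                 raw_response = raw),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat("<verdict> ", x$decision,
      " (effective label: ", x$effective_label, ")\n", sep = "")
  invisible(x)
}

# ---- cohort-scale adjudication ----

#' Adjudicate a cohort of profiles
#'
#' Builds one prompt bundle per profile, queries the backend, and parses
#' each response. With `checkpoint_path`, results stream to JSONL as they
#' are produced and a rerun resumes idempotently: persons already present
#' in the checkpoint are skipped and their stored results reused, so an
#' interrupted run finishes to the same output as an uninterrupted one.
#' Per-person backend failures are recorded (decision
#' `"error"` in the failure report) and the run continues.
#'
#' @param profiles list of `patient_profile` objects.
#' @param config the [keeper_config()] used for extraction.
#' @param variant one of [prompt_variants()].
#' @param backend an `llm_backend` (default [mock_backend()]).
#' @param params [backend_params()].
#' @param grouping category -> display-group mapping.
#' @param few_shot_examples see [build_messages()].
#' @param checkpoint_path optional JSONL checkpoint/stream path.
#' @return data.table of class `adjudication_results` with columns
#'   `person_id, variant, model_name, decision, effective_label,
#'   raw_response`, in profile order; failures (if any) in
#'   `attr(, "failures")`.
#' @export
adjudicate_cohort <- function(profiles, config, variant = "V4_uncertainty",
                              backend = mock_backend(),
                              params = backend_params(),
                              grouping = default_profile_grouping(),
                              few_shot_examples = NULL,
                              checkpoint_path = NULL) {
  if (!length(profiles)) stop("profiles must be non-empty")
  stopifnot(inherits(config, "keeper_config"))
  system_prompt <- build_system_prompt(variant, config$disease_name)
  prefix <- list(list(role = "system", content = system_prompt))
  if (variant == "V5_few_shot") {
    if (is.null(few_shot_examples))
      few_shot_examples <- default_few_shot_examples(
        config$disease_name, config$conceptual_definition)
    if (!length(few_shot_examples))
      stop("the few-shot variant requires >= 1 example")
    for (ex in few_shot_examples)
      prefix <- c(prefix,
                  list(list(role = "user", content = ex$main_prompt),
                       list(role = "assistant", content = ex$ideal_response)))
  }

  done <- data.table::data.table()
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    recs <- read_jsonl(checkpoint_path)
    if (length(recs))
      done <- data.table::rbindlist(lapply(recs, data.table::as.data.table))
  }
  done_ids <- if (nrow(done)) done$person_id else integer(0)

  buffer <- list()
  flush <- function() {
    if (length(buffer) && !is.null(checkpoint_path)) {
      write_jsonl(buffer, checkpoint_path,
                  append = file.exists(checkpoint_path))
    }
    buffer <<- list()
  }
  rows <- vector("list", length(profiles))
  failures <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (p$person_id %in% done_ids) {
      rows[[i]] <- done[done$person_id == p$person_id][1L]
      next
    }
    rec <- tryCatch({
      main <- build_main_prompt(serialize_profile(p, grouping),
                                config$disease_name,
                                config$conceptual_definition)
      msgs <- c(prefix, list(list(role = "user", content = main)))
      raw <- complete(backend, msgs, params)
      v <- parse_response(raw)
      list(person_id = p$person_id, variant = variant,
           model_name = params$model_name, decision = v$decision,
           effective_label = v$effective_label, raw_response = v$raw_response)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(person_id = p$person_id, message = conditionMessage(e))
      NULL
    })
    if (is.null(rec)) next
    rows[[i]] <- data.table::as.data.table(rec)
    buffer[[length(buffer) + 1L]] <- rec
    if (length(buffer) >= 500L) flush()
  }
  flush()
  if (length(failures))
    warning(length(failures), " adjudication(s) failed; see attr(, ",
            "'failures')")
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))],
                               use.names = TRUE)
  data.table::setattr(out, "failures", failures)
  data.table::setattr(out, "class",
                      c("adjudication_results", class(out)))
  out[]
}

#' Read adjudication results from a JSONL stream
#'
#' @param path JSONL written by [adjudicate_cohort()].
#' @return data.table of results.
#' @export
read_adjudications <- function(path) {
  recs <- read_jsonl(path)
  data.table::rbindlist(lapply(recs, data.table::as.data.table))
}
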