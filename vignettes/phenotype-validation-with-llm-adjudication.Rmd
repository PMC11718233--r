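---
title: "Validating phenotype algorithms with standardized profiles and LLM adjudication"
author: "keeperllm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating phenotype algorithms with standardized profiles and LLM adjudication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Observational studies on claims and EHR data identify outcomes with
*phenotype algorithms* — code lists plus logic over a patient's coded
history. Whether an algorithm actually finds true cases in a particular
database is an empirical question, traditionally answered by manual chart
review of a small sample of flagged patients. That yields only a positive
predictive value (PPV), is expensive (chart review is commonly priced at
hundreds of dollars per case), and cannot estimate sensitivity unless
non-cases are reviewed too, which is rarely feasible for rare outcomes.

`keeperllm` implements an alternative pipeline:

1. **Standardized profile extraction.** For each cohort entrant, the
   package reduces the person's longitudinal OMOP-CDM record to a compact,
   clinically organized profile: per-category concept sets (symptoms,
   disease history, index diagnosis, laboratory workup, differential
   diagnoses, treatment, complications, comorbidities) restricted to
   index-anchored time windows.
2. **Prompt construction.** The profile is rendered to deterministic text
   and embedded in a staged chat prompt asking whether the patient truly
   had the disease on the index date.
3. **Adjudication.** A pluggable text-completion backend answers; the
   response's final "Summary" section is parsed into a binary verdict.
4. **Evaluation.** Verdicts are scored against gold standards (external
   review or leave-one-out majority votes), or used at scale as a *silver
   standard* over a deliberately over-inclusive high-sensitivity cohort,
   from which both PPV and sensitivity of any phenotype algorithm can be
   estimated with exact binomial confidence intervals.

Because real patient-level sources cannot be shared, the package includes a
seeded synthetic-data generator producing OMOP-shaped populations with
planted case structure, so the entire pipeline is exercised end to end
without any external data.

## Extraction model

A `keeper_config` holds one `keeper_category` per clinical-reasoning step.
Each category is a concept set (with OHDSI-style include-descendants /
exclude flags, expanded against the reflexive ancestry table), a set of
event domains, and a window in signed days relative to the index date.

Numerical conventions, fixed once and tested:

* **Windows are inclusive at both ends**, and day 0 is the index day.
  "Within 30 days before index" is `[-30, 0]`; "any point prior" is
  `(-Inf, -1]`. Index-day coding belongs with presentation; strictly-prior
  semantics for history avoid double-counting the index diagnosis itself.
* **Duplicate rows collapse.** Claims data repeat one line per billing
  row; identical `(concept, date)` pairs become one item with an
  occurrence count.
* **Deterministic ordering** everywhere: items sort by category
  (configuration order), date, then concept name; events tie-break by
  `(date, domain, concept_id)` with domains in alphabetical order; cohort
  entry events tie-break by smallest concept id on equal dates (the index
  date is unaffected).
* **Measurements without a recorded value** are rendered as
  "ordered, result not recorded" — in claims sources only a minority of
  laboratory orders carry results, and the distinction between "not done"
  and "result unavailable" is clinically meaningful.

The shipped osteoporosis and rheumatoid arthritis configurations under
`inst/extdata/` are **illustrative reconstructions at toy scale**, not
curated clinical concept sets; real deployments supply their own
`keeper_config` (YAML or JSON; unbounded window starts serialize as
`-.inf` / `"-Inf"`).

## Prompt staging

Six cumulative variants mirror an iterative prompt-engineering ladder:

| variant | adds |
|---|---|
| `V0_yes_no` | bare binary instruction + mandatory final `Summary:` section |
| `V1_discuss_evidence` | discuss evidence for and against |
| `V2_write_narrative` | write a clinical narrative consistent with the data |
| `V3_diagnosis_insufficient` | a diagnosis code alone is not sufficient evidence |
| `V4_uncertainty` | explicit guidance for handling uncertainty |
| `V5_few_shot` | two worked examples as extra chat messages (system text unchanged) |

Composition is strictly cumulative: every sentence of variant *k* appears
verbatim in variant *m > k* (property-tested). Wording lives in versioned
template files under `inst/prompts/` so tests can pin bytes; where no
canonical wording exists the phrasing is reconstructed in neutral language.
The few-shot examples are synthetic (one clear positive, one isolated-code
negative) and configurable per disease.

Profiles render with **relative days, not calendar dates**, keeping prompt
bytes stable across regenerated synthetic data and carrying no identifier
beyond the opaque person id (which itself never enters the prompt text).
Display groups combine related categories — symptoms, disease history,
comorbidities and risk factors all render under "Diagnoses recorded prior
to the visit" — and empty groups print an explicit "none recorded" line so
the adjudicator sees absence rather than omission.

## Backends and parsing

The backend contract is a single `complete(backend, messages, params)`
generic; the default parameters use temperature 0 so runs are
reproducible. Three backends ship:

* `mock_backend()` — fully deterministic and offline. It re-parses the
  profile text out of the prompt and answers "yes" iff at least
  `min_support_categories` (default 2) supporting display groups are
  non-empty, with an optional veto when alternative-diagnosis items
  outnumber supporting items. A bare diagnosis is always "no". This is a
  test instrument with a clinically shaped decision boundary, not an
  attempt to model any specific LLM.
* `replay_backend()` — byte-for-byte replay of recorded transcripts, for
  regression tests against any real model without network access.
* `http_backend()` — one neutral chat-completions request shape via the
  system `curl` binary, with bounded exponential-backoff retries; API keys
  are referenced by environment-variable name and never stored.

Response parsing is deliberately simple and total: locate the **last**
section headed `summary` (case-insensitive); scan it for whole-word
yes/no; exactly one keyword decides, both-or-neither is `indeterminate`;
without a summary header the final 200 characters are scanned. An
indeterminate verdict carries an effective label of "no" — the
conservative convention for unresolved output — and is additionally
counted separately in reports. Negation is intentionally not parsed; only
the explicit Summary keywords count.

Cohort-scale adjudication streams results to JSONL and resumes
idempotently from that checkpoint, since real hosted-model runs over tens
of thousands of profiles take days and fail partway.

## Evaluation statistics

* Adjudicators are binary, so the ROC has a single operating point and
  **AUC = (sensitivity + specificity) / 2**.
* Confidence intervals default to **Clopper–Pearson exact** (beta
  quantiles; lower bound exactly 0 at zero successes, upper exactly 1 at
  *n*), consistent with the asymmetric intervals customary for validation
  studies; Wilson is available as an option. The implementation is checked
  against `stats::binom.test` to 1e-9 and for empirical coverage at the
  nominal level.
* **Majority-vote gold standards** require a complete person-by-reviewer
  block and at least three reviewers; when evaluating a reviewer their own
  column is left out, so their labels never influence their own gold
  standard (perturbation-tested). An exact 2–2 tie resolves to negative
  and is flagged; the tie rule is a package decision, consistent with the
  conservative indeterminate-to-no convention.
* **Operating characteristics** against a silver standard report
  PPV = tp / n_flagged and sensitivity = tp / n_silver_positives with
  their intervals and all underlying counts, satisfying the exact
  identities `ppv * n_flagged == tp` and
  `sensitivity * n_silver_pos == tp`.
* Display rounding is half-away-from-zero at one decimal for percentages
  and two for AUC; machine outputs keep full precision.

## The synthetic generator

`simulate_population()` emulates the structure the pipeline consumes — not
any real database's marginals. Per person: a Bernoulli(prevalence) case
flag; cases receive one descendant diagnosis code at a uniformly drawn
index date, each symptom and laboratory order with probability
`p_symptom_given_case` in the 30 days up to index, each comorbidity with
probability `p_comorbidity_given_case` 31–1800 days before, and each
treatment with probability `p_treatment_given_case` 0–90 days after —
windows aligned with the default extraction windows so planted signal
falls where extraction looks. Non-cases may receive an isolated spurious
diagnosis (`p_spurious_diagnosis_given_noncase`, default 0.05) or a
differential diagnosis plus its paired treatment
(`p_differential_given_noncase`, default 0.2), the latter as deliberate
false-positive bait. Everyone accrues Poisson background events (mean 5)
from unrelated concepts, and measurement events carry a numeric result
with probability 0.3, the rough fraction at which claims sources record
laboratory results.

Defaults (n = 2000, prevalence 0.1, symptom 0.8 / treatment 0.7 /
comorbidity 0.5) were chosen once as plausible for a moderately prevalent
chronic disease with good care continuity; the lab-order planting reuses
`p_symptom_given_case` because a diagnostic workup accompanies
presentation and the parameter set deliberately stays small.

Reproducibility: person *i* draws from a substream derived from
`(seed, i)`, so stores are byte-identical across runs and existing persons
are unchanged when the population grows.

**What passing tests do and do not show.** The planted structure is
cleanly separable — cases carry support, spurious non-cases carry none —
so the mock adjudicator attains near-ceiling accuracy on simulated
cohorts. Pipeline tests therefore validate extraction, prompting, parsing
and the estimation machinery, *not* adjudication difficulty on real
records, where missing results, coding churn and genuine clinical
ambiguity dominate. The generator also omits enrollment spans, visit
structure, provider attributes and code churn.

## Analytic check of the silver-standard estimator

Using planted truth as the silver standard, the first-occurrence
diagnosis algorithm flags every case plus non-cases with a spurious code,
so the planted PPV is

PPV = p / (p + (1 − p) q),

with p the prevalence and q the spurious-diagnosis probability
(≈ 0.690 at the defaults), and planted sensitivity is exactly 1. The
acceptance suite verifies that the estimator's 95% intervals cover these
planted values in at least 90% of 200 seeded replicates at n = 2000 —
conditional on the flagged count, the true-positive count is binomial, so
Clopper–Pearson coverage applies directly.

## Problem sizes

The test suite and acceptance script use populations of 40–2000 persons
for unit and recovery checks, 200 replicates for coverage, 1,000 random
instances per brute-force oracle comparison, and one 190,000-person
population from which a 25,000-person high-sensitivity sample is
extracted, prompted and mock-adjudicated in a single run — sizes chosen to
exercise cohort-scale code paths while keeping a full run in minutes on
one CPU.

## Known limitations

* Phenotype algorithms are limited to the first-occurrence skeleton
  (entry concept set + domain); full OHDSI cohort-definition semantics
  (inclusion windows, washout) are out of scope.
* The high-sensitivity cohort's index date for non-diagnosis entrants is
  the earliest qualifying union event — a package decision where no
  standard convention exists.
* The HTTP backend is a thin adapter and is not exercised by the offline
  test suite; the mock and replay backends carry all contract tests.
* Concept hierarchies in the toy vocabulary are two levels deep; the
  expansion machinery itself is tested on deeper random DAGs.
* Token accounting, cost estimation and automated prompt optimization are
  deliberately absent.
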