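# keeperllm

Phenotype-algorithm validation for OMOP CDM data: standardized patient
profile extraction, staged LLM prompting, pluggable adjudication backends
(including a deterministic offline mock), and estimation of operating
characteristics against gold and silver standards.

## Who this is for

Observational researchers working in the OMOP Common Data Model who need
to know how well a phenotype algorithm (a code list plus logic, e.g.
"first diagnosis mapping to the standard Osteoporosis concept or any
descendant") identifies true cases in their database. Manual chart review
of flagged cases yields only a PPV; reviewing enough non-cases for
sensitivity is usually infeasible. This package operationalizes a
scalable alternative: extract a compact, clinically organized profile per
patient from structured data, let a text-completion model adjudicate case
status, and — because automated review scales to tens of thousands of
patients — estimate **both PPV and sensitivity** of any algorithm against
the resulting silver standard.

## The method in brief

For a cohort entrant with index date $t_0$, extraction collects, per
clinical category $c$ with concept set $S_c$ and window
$[t_0 + a_c,\; t_0 + b_c]$ (inclusive; $a_c = -\infty$ allowed), every
event whose concept lies in the descendant-expanded $S_c$. The rendered
profile is embedded in a staged system prompt (binary instruction, then
cumulatively: discuss evidence, write a narrative, "a diagnosis alone is
insufficient", uncertainty handling, optional few-shot examples) and the
backend's response is parsed by scanning the final `Summary:` section for
a whole-word yes/no; unresolved output conservatively counts as "no".

For a binary adjudicator, AUC $= (\mathrm{Se} + \mathrm{Sp})/2$. Against
a silver standard over a high-sensitivity roster,

$$\widehat{\mathrm{PPV}} = \frac{tp}{n_\mathrm{flagged}}, \qquad
\widehat{\mathrm{Se}} = \frac{tp}{n_\mathrm{silver+}},$$

each with Clopper–Pearson exact intervals
($\mathrm{qbeta}(\alpha/2;\,x,\,n-x+1)$,
$\mathrm{qbeta}(1-\alpha/2;\,x+1,\,n-x)$). Gold standards from multiple
reviewers use leave-one-out majority votes (ties resolve to negative,
flagged).

A seeded synthetic-data module generates OMOP-shaped populations with
planted case structure so the full pipeline runs and is tested with no
external data.

## Worked example

```r
library(keeperllm)

tpl <- osteoporosis_template()                       # toy disease template
sim <- simulate_population(tpl, simulation_params(n_persons = 2000, seed = 42))
sim$store
#> <cdm_store>
#>   persons:  2000
#>   events:   12228 (condition: 3381, drug: 2599, measurement: 2324, ...)
#>   concepts: 27; ancestry rows: 30

# phenotype algorithm: first diagnosis under the root concept
cs <- concept_set("osteoporosis diagnosis",
                  data.frame(concept_id = 1000L, include_descendants = TRUE))
cohort <- first_occurrence_cohort(sim$store, cs)     # 298 entrants

config   <- template_keeper_config(tpl)
profiles <- extract_profiles(sim$store, cohort, config)
cat(serialize_profile(profiles[[2]]))
#> Patient: 45 year old female.
#>
#> Diagnoses recorded prior to the visit:
#> - none recorded
#>
#> Diagnoses recorded at the visit:
#> - Senile osteoporosis (day 0)
#> ...

res   <- adjudicate_cohort(profiles, config, backend = mock_backend())
truth <- sim$labels[sim$labels$person_id %in% cohort$person_id]
adjudication_metrics(res, truth)
#> <metrics_result>
#>   sensitivity: 99.0% (96.5-99.9%)  [n_pos=202]
#>   specificity: 100.0% (96.2-100.0%)  [n_neg=96]
#>   AUC:         1.00
```

The profile above is an isolated diagnosis code with no supporting
findings — the mock adjudicator (and the staged prompt's "diagnosis alone
is insufficient" instruction) treats exactly this pattern as a likely
false positive. With planted truth as the reference, the algorithm's
operating characteristics over the whole population:

```r
roster <- sim$labels$person_id
operating_characteristics(
  data.frame(person_id = roster, label = sim$labels$true_case),
  data.frame(person_id = roster, label = roster %in% cohort$person_id))
#> <operating_characteristics>
#>   PPV:         67.8% (95% CI 62.2-73.1%)  [tp=202 / flagged=298]
#>   sensitivity: 100.0% (95% CI 98.2-100.0%)  [tp=202 / silver+=202]
```

The PPV is below 1 because some non-cases carry a spurious isolated
diagnosis; sensitivity is 1 because every planted case receives an index
code. Swap `mock_backend()` for `http_backend()` (or `replay_backend()`
for recorded transcripts) to adjudicate with a hosted model.

A staged command-line pipeline
(`simulate → cohort → extract → prompt → adjudicate → evaluate →
characterize`) ships as `inst/cli/keeper-pipeline.R`; see
`?keeper_cli`.

## Package layout

- `R/omop_store.R` — minimal OMOP v5.x table bundle, CSV/Parquet IO
- `R/synthetic_data.R` — disease templates, seeded population generator
- `R/phenotype_cohort.R` — concept sets, first-occurrence and
  high-sensitivity cohorts
- `R/keeper_extract.R` — category/window profile extraction, config IO
- `R/prompt_builder.R` — profile serialization, staged prompts, few-shot
- `R/llm_adjudicator.R` — backend contract, mock/replay/HTTP backends,
  response parsing, checkpointed cohort adjudication
- `R/evaluation.R` — confusion/metrics/intervals, majority votes,
  operating characteristics, reports
- `R/cli_config.R` — run configs, staged CLI, manifests
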