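# Illustrative extraction configuration reconstructed from in-text
# examples at toy scale; not a clinically curated concept-set release.
disease_name: osteoporosis
conceptual_definition: a skeletal disorder characterized by decreased bone density
  and strength, leading to fragile bones and an increased risk of fractures
categories:
- category_name: clinical_presentation
  domains:
  - condition
  window:
    start_offset_days: -30.0
    end_offset_days: 0.0
  concept_set:
    name: symptoms
    items:
    - concept_id: 2001
      include_descendants: no
      is_excluded: no
    - concept_id: 2002
      include_descendants: no
      is_excluded: no
    - concept_id: 2003
      include_descendants: no
      is_excluded: no
- category_name: disease_history
  domains:
  - condition
  window:
    start_offset_days: -Inf
    end_offset_days: -1.0
  concept_set:
    name: prior diagnoses
    items:
    - concept_id: 1000
      include_descendants: yes
      is_excluded: no
- category_name: preliminary_diagnosis
  domains:
  - condition
  window:
    start_offset_days: 0.0
    end_offset_days: 0.0
  concept_set:
    name: index diagnosis
    items:
    - concept_id: 1000
      include_descendants: yes
      is_excluded: no
- category_name: diagnostic_procedures
  domains:
  - measurement
  window:
    start_offset_days: -30.0
    end_offset_days: 30.0
  concept_set:
    name: laboratory tests
    items:
    - concept_id: 4001
      include_descendants: no
      is_excluded: no
    - concept_id: 4002
      include_descendants: no
      is_excluded: no
- category_name: differential_diagnoses
  domains:
  - condition
  window:
    start_offset_days: -90.0
    end_offset_days: 90.0
  concept_set:
    name: differential diagnoses
    items:
    - concept_id: 2201
      include_descendants: no
      is_excluded: no
    - concept_id: 2202
      include_descendants: no
      is_excluded: no
- category_name: treatment
  domains:
  - drug
  window:
    start_offset_days: 0.0
    end_offset_days: 90.0
  concept_set:
    name: treatments
    items:
    - concept_id: 3001
      include_descendants: no
      is_excluded: no
    - concept_id: 3002
      include_descendants: no
      is_excluded: no
- category_name: comorbidities
  domains:
  - condition
  window:
    start_offset_days: -Inf
    end_offset_days: -1.0
  concept_set:
    name: comorbidities
    items:
    - concept_id: 2101
      include_descendants: no
      is_excluded: no
    - concept_id: 2102
      include_descendants: no
      is_excluded: no

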