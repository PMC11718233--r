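# Illustrative extraction configuration reconstructed from in-text
# examples at toy scale; not a clinically curated concept-set release.
disease_name: rheumatoid arthritis
conceptual_definition: a chronic autoimmune inflammatory disease primarily affecting
  synovial joints, presenting with symmetric polyarthritis, morning stiffness, and
  elevated inflammatory markers
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
    - concept_id: 2501
      include_descendants: no
      is_excluded: no
    - concept_id: 2502
      include_descendants: no
      is_excluded: no
    - concept_id: 2503
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
    - concept_id: 1500
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
    - concept_id: 1500
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
    - concept_id: 4501
      include_descendants: no
      is_excluded: no
    - concept_id: 4502
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
    - concept_id: 2701
      include_descendants: no
      is_excluded: no
    - concept_id: 2702
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
    - concept_id: 3501
      include_descendants: no
      is_excluded: no
    - concept_id: 3502
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
    - concept_id: 2601
      include_descendants: no
      is_excluded: no
    - concept_id: 2602
      include_descendants: no
      is_excluded: no

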