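phenotype_name: acute appendicitis (synthetic)
concept_sets:
  relevant_conditions:
  - concept_id: 1000
    include_descendants: yes
    excluded: no
  - concept_id: 1450
    include_descendants: yes
    excluded: no
  - concept_id: 1510
    include_descendants: no
    excluded: no
  family_history:
  - concept_id: 5100
    include_descendants: no
    excluded: no
  competing_conditions:
  - concept_id: 1300
    include_descendants: yes
    excluded: no
  - concept_id: 1310
    include_descendants: yes
    excluded: no
  - concept_id: 1450
    include_descendants: yes
    excluded: no
  - concept_id: 1510
    include_descendants: no
    excluded: no
  diagnostic_procedures:
  - concept_id: 3100
    include_descendants: no
    excluded: no
  - concept_id: 3300
    include_descendants: no
    excluded: no
  lab_panel:
  - concept_id: 4100
    include_descendants: no
    excluded: no
  - concept_id: 4200
    include_descendants: no
    excluded: no
  - concept_id: 4300
    include_descendants: no
    excluded: no
  treatment_procedures:
  - concept_id: 3200
    include_descendants: no
    excluded: no
  - concept_id: 3400
    include_descendants: no
    excluded: no
  relevant_drugs:
  - concept_id: 2000
    include_descendants: yes
    excluded: no
  - concept_id: 2300
    include_descendants: yes
    excluded: no
  - concept_id: 2600
    include_descendants: yes
    excluded: no
  complication_conditions:
  - concept_id: 1110
    include_descendants: no
    excluded: no
  - concept_id: 1400
    include_descendants: no
    excluded: no
elements:
- element: presentation
  domains:
  - condition
  concept_set: relevant_conditions
  window:
    lo: 0
    hi: 0
- element: prior_history
  domains:
  - condition
  concept_set: relevant_conditions
  window:
    lo: -inf
    hi: -1
- element: comorbidities_risk_factors
  domains:
  - observation
  concept_set: family_history
  window:
    lo: -inf
    hi: -1
- element: competing_diagnoses
  domains:
  - condition
  concept_set: competing_conditions
  window:
    lo: 1
    hi: +inf
- element: diagnostic_procedures
  domains:
  - procedure
  concept_set: diagnostic_procedures
  window:
    lo: -inf
    hi: +inf
- element: lab_tests
  domains:
  - measurement
  concept_set: lab_panel
  window:
    lo: -inf
    hi: +inf
- element: treatment_procedures
  domains:
  - procedure
  concept_set: treatment_procedures
  window:
    lo: 0
    hi: +inf
- element: medications
  domains:
  - drug
  concept_set: relevant_drugs
  window:
    lo: 0
    hi: +inf
- element: complications
  domains:
  - condition
  concept_set: complication_conditions
  window:
    lo: 1
    hi: +inf
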