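# Guideline profile for acute oral toxicity (OECD 401-style single-dose
# design). Housing/feeding and stability-verification questions do not apply
# to acute studies; the corresponding properties are still declared so data
# present in an opinion can be captured.
guideline_id: OECD_401
endpoint: acute oral toxicity
study_kind: acute
concepts:
- name: Test method
  concepts:
  - name: Test substance
    properties:
    - name: identification
      value_type: text
    - name: purity
      value_type: text
    - name: source or origin
      value_type: text
    - name: physicochemical properties
      value_type: text
    - name: batch number
      value_type: text
    - name: homogeneity and stability
      value_type: boolean
  - name: Test condition
    concepts:
    - name: Oral administration
      properties:
      - name: route
        value_type: enum
        allowed_values: [gavage, diet, drinking water]
    properties:
    - name: dose levels
      value_type: text
      unit: mg/kg bw
    - name: dose-volume ml/kg bw
      value_type: numeric
      unit: ml/kg bw
    - name: observation period
      value_type: text
    - name: animals per group
      value_type: numeric
- name: Test animal
  properties:
  - name: species
    value_type: text
  - name: strain
    value_type: text
  - name: sex
    value_type: enum
    allowed_values: [male, female, male and female]
  - name: age value
    value_type: numeric
  - name: age unit
    value_type: enum
    allowed_values: [days, weeks, months, years]
  - name: body weight
    value_type: text
- name: Clinical observations
  properties:
  - name: moribund or dead animals prior to study termination
    value_type: boolean
  - name: mortality rate
    value_type: text
- name: Results
  properties:
  - name: endpoints and methods
    value_type: text
  - name: results description
    value_type: text
  - name: statistical methods
    value_type: text
  - name: quantitative results reliability
    value_type: text
  - name: study design appropriateness
    value_type: text
defaults:
  Test method/Test condition/observation period: 14 days
  Results/study design appropriateness: guideline-conformant
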