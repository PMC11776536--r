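# Guideline profile for OECD test guideline No. 408: 90-day repeated-dose
# oral toxicity in rodents. Concepts (capitalized) shape the hierarchy; value
# properties (lowercase) carry typed data. The tree covers the properties the
# reliability rulebook and the liver screen consult; it is extensible.
guideline_id: OECD_408
endpoint: repeated-dose oral toxicity (90-day, rodent)
study_kind: repeated_dose
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
      unit: mg/kg bw/day
    - name: dose-volume ml/kg bw
      value_type: numeric
      unit: ml/kg bw
    - name: repeated administration scheme
      value_type: text
    - name: duration of exposure
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
  - name: housing conditions
    value_type: text
  - name: feeding conditions
    value_type: text
- name: Clinical observations
  properties:
  - name: moribund or dead animals prior to study termination
    value_type: boolean
  - name: mortality rate
    value_type: text
- name: Clinical biochemistry
  concepts:
  - name: Hepatocellular effect
    properties:
    - name: alt
      value_type: text
    - name: ast
      value_type: text
    - name: alp
      value_type: text
    - name: ggt
      value_type: text
    - name: sorbitol dehydrogenase
      value_type: text
    - name: total bilirubin
      value_type: text
    - name: total cholesterol
      value_type: text
    - name: fasting triglycerides
      value_type: text
    - name: total protein
      value_type: text
    - name: albumin
      value_type: text
- name: Pathology
  concepts:
  - name: Histopathology
    properties:
    - name: hepatic necrosis
      value_type: boolean
    - name: hepatocellular hypertrophy
      value_type: boolean
    - name: findings
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
  Test method/Test condition/repeated administration scheme: 7 days/week
  Test method/Test condition/duration of exposure: 90 days
  Results/study design appropriateness: guideline-conformant
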