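# ToxRTool question catalogue and declarative answer-derivation rulebook.
# 21 questions in 5 criteria groups; weight "red" marks questions that must
# score 1 for a study to reach reliability category 1 or 2. Most questions are
# evidence-presence checks over profile paths (combinator ANY/ALL); three have
# documented special derivations implemented in code:
#   frequency_duration  (III.3) - ALL of scheme+duration, satisfiable by the
#                                 profile defaults when the opinion omits them
#   controls            (III.4) - control & recovery block present, else a "0"
#                                 dose level serves as the negative control
#   administration_scheme (III.6) - route-dependent: gavage accepts
#                                 homogeneity/stability OR dose-volume;
#                                 diet/drinking water require homogeneity and
#                                 stability
questions:
- id: I.1
  group: I
  text: Was the test substance identified?
  weight: red
  applicability: all
  combinator: ANY
  paths: ["Test method/Test substance/identification"]
- id: I.2
  group: I
  text: Is the purity of the substance given?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Test method/Test substance/purity"]
- id: I.3
  group: I
  text: Is information on the source/origin of the substance given?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Test method/Test substance/source or origin"]
- id: I.4
  group: I
  text: >-
    Is all information on the nature and/or physico-chemical properties of the
    test item given, which you deem indispensable for judging the data?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Test method/Test substance/physicochemical properties"]
- id: II.1
  group: II
  text: Is the species given?
  weight: red
  applicability: all
  combinator: ANY
  paths: ["Test animal/species"]
- id: II.2
  group: II
  text: Is the sex of the test organism given?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Test animal/sex"]
- id: II.3
  group: II
  text: >-
    Is information given on the strain of test animal plus, if considered
    necessary to judge the study, other specifications?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Test animal/strain"]
- id: II.4
  group: II
  text: Is age or body weight of the test organisms at the start of the study given?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Test animal/age value", "Test animal/body weight"]
- id: II.5
  group: II
  text: >-
    For repeated dose toxicity studies only: Is information given on the
    housing or feeding conditions?
  weight: normal
  applicability: repeated_dose
  combinator: ANY
  paths: ["Test animal/housing conditions", "Test animal/feeding conditions"]
- id: III.1
  group: III
  text: Is the administration route given?
  weight: red
  applicability: all
  combinator: ANY
  paths: ["Test method/Test condition/Oral administration/route"]
- id: III.2
  group: III
  text: Are doses administered or concentrations in application media given?
  weight: red
  applicability: all
  combinator: ANY
  paths: ["Test method/Test condition/dose levels"]
- id: III.3
  group: III
  text: >-
    Are frequency and duration of exposure as well as time-points of
    observations explained?
  weight: red
  applicability: all
  rule: frequency_duration
  combinator: ALL
  paths:
  - "Test method/Test condition/repeated administration scheme"
  - "Test method/Test condition/duration of exposure"
  acute_paths:
  - "Test method/Test condition/observation period"
- id: III.4
  group: III
  text: Were negative and positive controls included?
  weight: red
  applicability: all
  rule: controls
  paths: ["Test method/Test condition/dose levels"]
- id: III.5
  group: III
  text: Is the number of animals per group given?
  weight: red
  applicability: all
  combinator: ANY
  paths: ["Test method/Test condition/animals per group"]
- id: III.6
  group: III
  text: Are sufficient details of the administration scheme given to judge the study?
  weight: normal
  applicability: all
  rule: administration_scheme
  paths:
  - "Test method/Test condition/Oral administration/route"
  - "Test method/Test substance/homogeneity and stability"
  - "Test method/Test condition/dose-volume ml\\/kg bw"
- id: III.7
  group: III
  text: >-
    For inhalation studies and repeated dose toxicity studies only: Were
    achieved concentrations analytically verified or was stability of the test
    substance otherwise ensured is made plausible?
  weight: normal
  applicability: inhalation_or_repeated_dose
  combinator: ANY
  paths: ["Test method/Test substance/homogeneity and stability"]
- id: IV.1
  group: IV
  text: >-
    Are the study endpoint(s) and their method(s) of determination clearly
    described?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Results/endpoints and methods"]
- id: IV.2
  group: IV
  text: >-
    Is the description of the study results for all endpoints investigated
    transparent and complete?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Results/results description"]
- id: IV.3
  group: IV
  text: >-
    Are the statistical methods applied for data analysis given and applied in
    a transparent manner?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Results/statistical methods"]
- id: V.1
  group: V
  text: >-
    Is the study design chosen appropriate for obtaining the substance-specific
    data aimed at?
  weight: red
  applicability: all
  combinator: ANY
  paths: ["Results/study design appropriateness"]
- id: V.2
  group: V
  text: Are the quantitative study results reliable?
  weight: normal
  applicability: all
  combinator: ANY
  paths: ["Results/quantitative results reliability"]
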