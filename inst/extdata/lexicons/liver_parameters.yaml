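# Canonical liver-toxicity parameter lexicon: the screening table's columns
# plus the additional serum markers used by the liver filters (sorbitol
# dehydrogenase, total protein, albumin, HDL, LDL). Synonym sets are pairwise
# disjoint; lookup is case-insensitive. User lexicons may extend this file to
# other organs.
parameters:
- canonical: ALT
  ec_number: "2.6.1.2"
  synonyms:
  - alanine aminotransferase
  - serum glutamate-pyruvate transaminase
  - SGPT
  - GPT
  - ALAT
- canonical: AST
  ec_number: "2.6.1.1"
  synonyms:
  - aspartate aminotransferase
  - serum glutamate-oxaloacetate transaminase
  - SGOT
  - GOT
  - ASAT
- canonical: ALP
  ec_number: "3.1.3.1"
  synonyms:
  - alkaline phosphatase
  - AP
  - ALKP
- canonical: GGT
  ec_number: "2.3.2.1"
  synonyms:
  - gamma-glutamyl transpeptidase
  - gamma-glutamyltransferase
  - gamma GT
- canonical: sorbitol dehydrogenase
  ec_number: "1.1.1.14"
  synonyms:
  - SDH
  - iditol dehydrogenase
- canonical: cholesterol
  synonyms:
  - total cholesterol
  - serum cholesterol
- canonical: triglycerides
  synonyms:
  - fasting triglycerides
  - serum triglycerides
  - triacylglycerols
- canonical: phospholipids
  synonyms:
  - serum phospholipids
- canonical: bilirubin
  synonyms:
  - total bilirubin
  - serum bilirubin
- canonical: hepatic fat
  synonyms:
  - liver fat
  - hepatic lipid accumulation
  - fatty liver
- canonical: hepatocellular hypertrophy
  synonyms:
  - liver cell hypertrophy
  - hepatocyte hypertrophy
- canonical: hepatic necrosis
  synonyms:
  - hepatocellular necrosis
  - liver necrosis
  - necrosis
- canonical: total protein
  synonyms:
  - serum total protein
- canonical: albumin
  synonyms:
  - serum albumin
- canonical: HDL
  synonyms:
  - high-density lipoprotein
- canonical: LDL
  synonyms:
  - low-density lipoprotein
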