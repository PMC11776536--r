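# toxinkg

Historical animal safety data on cosmetic ingredients — 90-day repeated-dose
toxicity studies reported in regulatory scientific opinions — is locked in
prose. Since the EU ban on animal testing for cosmetics, that legacy data is
the primary *in vivo* evidence available for next-generation (animal-free)
risk assessment, and reusing it requires making it machine-processable.
`toxinkg` is an R toolkit for that job, aimed at regulatory toxicologists
and cheminformatics engineers building knowledge-graph-backed hazard
screens. It provides:

* a **guideline-profiled data model**: OECD test guidelines decomposed into
  trees of concepts (capitalized structural nodes) and typed, lowercase
  value properties, against which study records are validated;
* an **automated Klimisch reliability engine** implementing the 21-question
  ToxRTool checklist. With question scores $q_i \in \{0,1\}$ and
  $S=\sum_i q_i$, the initial category is 1 if $S \ge 18$, 2 if
  $13 \le S \le 17$, else 3; any failed **red** question (I.1, II.1,
  III.1–III.5, V.1) forbids categories 1–2 in the revised category.
  Answers are derived from structured evidence paths, with
  guideline-conformance defaults (e.g. "7 days/week", "90 days") tracked by
  provenance;
* **liver-toxicant filters** over structured findings, with
  parameter-synonym (ALT = SGPT = GPT = ALAT) and direction-keyword
  (increase = raise = higher) lexicons and footnote-derived qualifier
  flags;
* **chemical identity services**: canonical SMILES (Open Babel), CAS
  check-digit validation, punctuation-robust fuzzy name search, and
  structural-alert assignment by set Dice similarity
  $D(A,B) = 2|A\cap B|/(|A|+|B|)$ with an inclusive 0.5 threshold;
* an **RDF knowledge graph**: quads in named graphs (`internal`,
  `ontology`, `external_links`, `inferred`), deterministic IRI minting,
  Turtle/TriG/N-Quads round-tripping, label-based `sameAs` linking, and
  "is affected by" inference that counts adverse effects shared between an
  opinion's observations and a disease's effect profile (closed under
  `is_a` inheritance).

## Worked example

```r
library(toxinkg)

ds <- load_screening_table()           # packaged 53-ingredient screening table
ds
#> <toxin_dataset> 53 compounds, 53 opinions, 2 studies, 135 effect entries; 0 violations

# Which ingredients disturb ALT? Query by any synonym; exclude the one
# non-OECD-qualified finding (the fixture-documented reference policy).
alt <- liver_query(ds, parameter = "SGPT", direction = "any",
                   exclude_qualifiers = "non_OECD")
nrow(alt)
#> [1] 18

# Score the packaged 90-day study for Basic Red 51:
score_dataset(ds)[["basic-red-51-rdt-1"]]
#> <reliability_result> basic-red-51-rdt-1
#>   sum: 21  initial: 1  revised: 1
#>   defaults used for: III.3, V.1

# Build the knowledge graph, link it to the ontology fixture, infer links:
onto <- read_turtle(system.file("extdata", "mini_ontology.ttl",
                                package = "toxinkg"))
kg <- infer_affected_by(link_same_as(build_kg(ds), onto), min_shared = 2)
kg
#> <kgraph> 1187 quads
#>    external_links : 32
#>    inferred : 16
#>    internal : 1080
#>    ontology : 59

head(affected_by_links(kg), 1)
#>                                            subject                              entity shared_count
#> 1 http://example.org/toxin/opinion/op-basic-red-51 http://example.org/txpo/cholestasis            3

# Competency question: given these observed effects, which toxic process?
competency_query(kg, "q1_effects_to_processes", list(
  effects = c("increased blood ALP concentration",
              "presence of GGT in blood", "necrosis")))
#>                                entity             label shared_count
#> 1 http://example.org/txpo/cholestasis liver cholestasis            3
```

Reading the output: the sum of 21 satisfied checklist questions puts the
Basic Red 51 study in Klimisch category 1 (reliable without restriction),
with two answers resting on flagged defaults. The ALT screen returns 18
distinct ingredients under the documented qualifier policy. The inference
layer links the Basic Red 51 opinion to liver cholestasis because three of
its observations (increased blood ALP, presence of GGT, hepatocellular
necrosis) match the cholestasis effect profile — and the first competency
query ranks cholestasis first for exactly that observation set.

A command-line wrapper ships in `inst/cli/toxinkg`
(`toxinkg filter --parameter ALT --direction any`, `toxinkg score`,
`toxinkg build-kg --out kg.trig`, `toxinkg query --kind q1 ...`).

## Repository layout

* `R/` — data model, ingest, reliability engine, filters, chemistry, KG.
* `inst/extdata/` — guideline profiles, rulebook, lexicons, packaged
  fixtures (with a README documenting every transcription choice), mini
  ontology.
* `vignettes/toxinkg-methods.Rmd` — the methods write-up: models,
  parameters, design decisions, limitations.
* `tests/testthat/` — unit, property and end-to-end suites.
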