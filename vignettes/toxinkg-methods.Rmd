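---
title: "Methods: guideline-profiled curation, reliability scoring and knowledge-graph inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guideline-profiled curation, reliability scoring and knowledge-graph inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxinkg)
```

`toxinkg` curates repeated-dose toxicity findings on cosmetic ingredients
into a structured, machine-processable form and layers three analyses on
top: automated study-reliability (Klimisch) scoring, lexicon-based
hepatotoxicity screening, and an RDF knowledge graph with rule-based link
inference. This vignette explains the underlying models, the tunable
parameters and their defaults, what the synthetic data emulate, and the
design choices taken where the design was genuinely open.

## Guideline profiling: the data model

Regulatory test guidelines (OECD 408 for 90-day repeated-dose oral
toxicity; an acute oral profile) are decomposed into a tree of **concepts**
— structural nodes written with a capital letter, at most three levels deep
— and **value properties** — typed, lowercase leaf fields with units
(e.g. `dose-volume ml/kg bw` in ml/kg body weight) and value domains
(booleans are exactly `YES`/`NO`). A study record is a map from
slash-delimited concept paths to values; slashes inside property names are
escaped `\/` so the serialized path grammar is unambiguous. Profiles ship
as YAML data files, so adding an endpoint (toxicokinetics, skin absorption)
is additive, not a code change.

Validation is pure: `validate_record()` returns a violation table rather
than raising, and ingest retains invalid rows flagged — curators' own
comments and discrepancies are provenance, not noise to be dropped.
Age is stored as a numeric value plus a unit enum (`days`…`years`),
keeping numbers queryable.

Each record field carries a provenance tag: `paper` (transcribed from the
opinion), `default` (filled by the profile's guideline-conformance
defaults), or `expert`. Defaults for the 90-day profile assume a
`7 days/week` administration scheme and `90 days` exposure: omissions in
guideline studies are treated as unintentional, not as non-compliance. The
acute profile defaults its observation period to 14 days. We also default
`study design appropriateness` to guideline-conformant: a study run to an
OECD guideline is, by construction, an appropriate design for its endpoint,
and the corresponding checklist question would otherwise always fail on
structured data alone.

## Automated reliability scoring

The scoring engine implements the 21-question, five-group ToxRTool
checklist. Each question scores 0/1; eight questions (I.1, II.1,
III.1–III.5, V.1) are **red**: mandatory for reliability categories 1–2.
The initial category comes from the sum: ≥ 18 → category 1 (reliable
without restriction), 13–17 → category 2 (reliable with restriction),
< 13 → category 3 (not reliable).

Most questions are declarative evidence-presence checks (the
question-to-paths mapping is shipped as data, `rulebook.yaml`, with an
ANY/ALL combinator). Three have richer, documented derivations:

* **III.6 (administration-scheme detail)** is route-dependent: for oral
  gavage, homogeneity-and-stability data *or* a dose-volume in ml/kg bw
  suffice; for diet or drinking-water administration, homogeneity and
  stability are required.
* **III.4 (controls)** accepts the reliability block's control & recovery
  group data; failing that, a `0` entry among the dose levels counts as the
  negative control.
* **III.3 (frequency/duration)** may be satisfied by the profile defaults;
  answers that used a default are flagged, so rendered output can
  distinguish opinion-sourced evidence from assumptions.

Two readings of the red-question revision rule circulate: the checklist
footnote (a failed red question forbids categories 1 *and* 2 — revised
category 3) and a softer formulation (category 2 or 3 depending on the
sum). Both are implemented behind `red_fail_policy`
(`"three"`, the default, per the footnote; `"sum_capped_two"`). They are
deliberately not reconciled — the choice is visible in every output.

Two structural decisions where practice is unstated: questions
inapplicable to a study kind (II.5 housing/feeding for acute studies; III.7
stability verification for non-inhalation acute studies) are skipped and
not counted, while the 18/13 thresholds stay on the full 21-point scale —
matching how the checklist is applied in practice, where inapplicable
questions are simply not reachable rather than rescaled. And evidence
buried in narrative text (animal sex, purity stated only in
physico-chemical sections) is *not* mined: a question scores 0 unless the
datum appears as a structured field. Free-text interpretation is out of
scope by design; defaults exist precisely to bridge the resulting gaps for
red questions. Non-OECD studies are not scorable at all — their designs
lack the structured anchor points the rulebook consults.

## Liver-toxicant screening

Opinions name the same analyte many ways (`ALT` = `SGPT` = `GPT` = `ALAT`
= alanine aminotransferase) and describe shifts with many verbs. Two
data-file lexicons normalize findings before matching: a parameter-synonym
lexicon (the screening table's eleven columns plus sorbitol dehydrogenase,
total protein, albumin, HDL and LDL; synonym sets are pairwise disjoint and
case-insensitive) and a direction map
(`increase`/`raise`/`higher`/`elevated`; `decrease`/`lower`/`reduced`;
`change`/`differ`/`alter`). Cells printed with both verbs
("Increase/decrease") become the direction `mixed` — its own category so a
`pure_increase` query can never double-count an ambiguous finding, while
plain `increase`/`decrease` queries still match it.

Qualifier flags transcribe the source table's footnotes
(doubtful-or-unrelated, incidental, dermal, human, non-OECD, inhalation,
…). The default policy excludes nothing: counts reflect raw table
presence. The reference count of 18 ALT-affecting ingredients (the table
has 19 non-empty ALT cells) is reproduced by excluding the single
`non_OECD`-qualified ALT entry — consistent with a screen scoped to 90-day
guideline studies — and that policy is an explicit, configurable argument,
documented in the fixture README, never hard-coded.

## Chemical identity

Canonical SMILES generation is delegated to Open Babel (via ChemmineOB)
behind a small contract: idempotent, representation-invariant, parse
errors explicit, polymers rejected (two corpus ingredients are polymers
and carry no SMILES by design). CAS numbers are validated with the
standard check-digit rule; failures are warnings, since curated sources
contain legacy numbers. Name search normalizes case, punctuation
(`No.`/`No`/`No.15`) and whitespace, then ranks by normalized
edit-distance similarity; proportional mode keeps the best fraction of
entries *plus* every substring match (searching "yellow" always returns
every ingredient with "yellow" in its name), hard mode applies a fixed
similarity threshold.

Structural-alert assignment uses set-based Dice similarity over discrete
fingerprint feature sets, $D(A,B) = 2|A \cap B| / (|A|+|B|)$, with an
inclusive 0.5 threshold. The Dice computation itself is plain set algebra
implemented in-package — so the threshold rule is testable with synthetic
feature sets, independent of any chemistry engine — while feature sets for
real molecules come from hashed path fragments (Open Babel FP2). Whether
the upstream profiler uses set or weighted Dice is unspecified; set-based
is implemented and documented. Alert results are labelled preliminary
indicators: screening hints, not assessments. The live profiler API is out
of scope; the alert-profile map is pluggable data.

## The knowledge graph

Quads live in named graphs that encode origin: `internal` (mapped from the
curated dataset), `ontology` (imported fixture/ontology triples),
`external_links` (label-matched identity links) and `inferred` (reasoned
links). The separation is asserted in tests: no inferred or external quad
ever sits in `internal`, so every statement's origin stays traceable.

Mapping from tables to triples uses declarative, R2RML-inspired rules
(source table, subject template, predicate, object column/constant) —
inspired-by rather than spec-conformant, since there is no SQL layer here
and the mapping-language landscape is still consolidating. IRI minting is
deterministic: compounds are keyed by CAS number when present, else by
slugged name; the same dataset always builds the same graph. Serialized
output (Turtle, TriG, N-Quads) is canonically ordered and round-trips
exactly. Because no RDF library is available in this package's R
dependency set, the quad store and the (restrained) Turtle reader are
implemented in-package; the reader covers prefixes, `a`, predicate/object
lists and string literals — enough for ontology fixtures, documented as a
subset.

**sameAs** links are inferred from exact normalized-label equality
(case-insensitive, whitespace-collapsed) between internal and ontology
entities. Ambiguous matches emit all candidate links plus a warning:
linking errors are non-critical and better surfaced than suppressed.

**"is affected by"** links are inferred by counting adverse effects shared
between an opinion's observations and a disease/toxic-process *effect
profile*. Profiles collect the effects attached to an entity via
`has_context`, closed under `is_a` inheritance (a subtype such as NAFLD, a
lipidosis, carries the lipidosis-level effects). A link is emitted when
the shared count reaches `min_shared`, and the count is kept on the link
as likelihood evidence. The default `min_shared = 2` reflects that one
shared generic effect is weak evidence; the threshold is a parameter, not
a constant. Counting is done at **opinion** level (observations aggregate
over a compound's most recent opinion); study-level aggregation is a noted
variant, not the default.

A small alignment table bridges filter-space findings to ontology effect
labels — `(ALP, increase)` → "increased blood ALP concentration",
`(GGT, increase)` → "presence of GGT in blood", histopathology necrosis →
"necrosis" — so the two vocabularies meet on canonical tokens.

Three competency questions scope what the graph must answer: effects →
candidate toxic processes (ranked by shared-effect count, ties broken
deterministically by IRI); disease → impacted biological
processes/pathways (reachable over `has_part`/pathway-association edges
with `is_a` inheritance); toxic process → gene products participating in
its affected processes.

## Fixtures and the synthetic generator

The packaged screening table transcribes the published 53-ingredient
liver-toxicant table cell by cell (135 findings); the fixture README
records every footnote-to-flag choice, including the typographically
ambiguous ones. Corpus metadata reproduces the seven published
use-category totals (88 ingredients); ingredients beyond the 53 named ones
are placeholder-flagged synthetic stand-ins carrying no findings. The
example study records and the ontology miniature are likewise synthetic
reconstructions of published figure content, marked as such — none of
this is real opinion text, and passing tests on it demonstrates the
machinery, not the full corpus.

`generate_studies()` produces seeded, byte-reproducible study records. At
`completeness = 1` every evidence path the rulebook consults is filled, so
records score 21/21 — the generator's defaults encode a fully-reported
guideline study. Lower completeness drops a random field subset;
`defect_menu` removes named paths from every record, making targeted cases
(missing species → red II.1 failure → revised category 3) constructible.
What the generator does *not* emulate: narrative free text, inconsistent
terminology inside fields, multi-study opinions with conflicting findings
— so green tests here say nothing about free-text robustness, which is
explicitly out of scope.

## Numerical choices and problem sizes

All computations are exact integer/set arithmetic; there is no
optimization, no tolerance tuning, and the only randomness (the study
generator) is seed-controlled. Curation accuracy rounds half-up to an
integer percent. Degenerate inputs are defined: empty datasets yield empty
results; Dice over two empty sets is an error (undefined), over one empty
set it is 0; an out-of-range checklist sum is a contract error.

Test and acceptance runs use the shipped fixtures (53 compounds, 135
findings, ~60-triple ontology, ~1200-quad graph) and generator batches of
≤ 25 records — sizes chosen so the full pipeline, including the exhaustive
2^8-red-pattern × sum sweep against the brute-force scoring oracle, runs
in well under a minute.

## Known limitations

* Only two guideline profiles ship; other endpoints rely on the extension
  mechanism.
* The Turtle reader is a documented subset (no blank nodes, datatyped
  literals, or collections).
* No free-text mining: evidence must be structured, or it does not count.
* The ontology miniature stands in for real ontology imports; competency
  answers on it validate the inference machinery, not biological coverage.
* The live QSAR-profiler integration is stubbed as pluggable alert
  profiles; no external API is called.
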