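# Packaged fixtures

All files here are plain-text fixtures consumed by the loaders in
`R/fixtures.R`. Checksums are recorded in `checksums.csv` and verified at
load time.

## Liver-toxicant screening table (`screening_*.csv`)

`screening_compounds.csv`, `screening_effects.csv` and `screening_opinions.csv`
transcribe the published screening table of 53 cosmetic ingredients that
altered at least one liver-associated parameter in 90-day repeated-dose
studies. One `effects` row per non-empty compound x parameter cell:

* cells printed as a single direction verb become `increase` / `decrease`;
* cells printed with both verbs ("Increase/decrease") become `mixed` (their
  own direction, so pure-increase queries never double-count them);
* "Different" / "Altered" / "Change" become `change`;
* parenthetical notes become qualifier flags: `(non-OECD)` -> `non_OECD`,
  `(inhalation)` -> `inhalation`.

### Footnote-marker transcription

The source table marks cells with footnote symbols whose legend reads:
doubtful-or-unrelated, not-histopathologically-supported, incidental, dermal,
human, method-interference, SCCS-conclusion-only, adaptive-compensatory.
Marker-to-legend alignment is typographically ambiguous in some renderings;
this fixture adopts the assignment below (sanity-checked against compound
use: the zinc pyrithione finding is dermal, the vitamin A finding is human).
Every footnoted cell, with the flags chosen here:

| Compound | Parameter | Direction | Qualifier flags |
|---|---|---|---|
| Bis(butylbenzoate) diaminotriazine aminopropyltrisiloxane | ALT | change | doubtful_or_unrelated |
| Bis(butylbenzoate) diaminotriazine aminopropyltrisiloxane | AST | change | doubtful_or_unrelated |
| Butylphenyl methylpropional | ALT | increase | non_OECD |
| Butylphenyl methylpropional | hepatocellular hypertrophy | increase | non_OECD |
| Butylphenyl methylpropional | GGT | increase | non_OECD |
| Decamethylcyclopentasiloxane (D5) | GGT | increase | inhalation |
| N-Methyl-2-pyrrolidone | cholesterol | mixed | doubtful_or_unrelated |
| Phenoxyethanol | triglycerides | increase | doubtful_or_unrelated |
| Phenoxyethanol | ALT | increase | dermal; doubtful_or_unrelated |
| Phenoxyethanol | AST | decrease | dermal; doubtful_or_unrelated |
| Phenoxyethanol | GGT | increase | doubtful_or_unrelated |
| Triclosan | cholesterol | mixed | human |
| Triclosan | AST | mixed | doubtful_or_unrelated |
| Triclosan | bilirubin | decrease | human |
| Disperse blue 377 | triglycerides | decrease | dermal; doubtful_or_unrelated |
| Polysilicone-15 | AST | decrease | adaptive_compensatory |
| Polysilicone-15 | bilirubin | decrease | adaptive_compensatory |
| Polysilicone-15 | ALP | decrease | adaptive_compensatory |
| o-Phenylphenol (and salts) | ALT | decrease | sccs_conclusion_only |
| 2-Hydroxyethylamino-5-nitroanisole | ALT | change | method_interference |
| Acid orange 7 | bilirubin | increase | doubtful_or_unrelated |
| 1,2,4-Trihydroxybenzene | bilirubin | increase | method_interference |
| Vitamin a | cholesterol | increase | human |
| Zinc pyrithione | cholesterol | increase | dermal |
| Basic orange 31 | cholesterol | increase | incidental |
| Basic orange 31 | triglycerides | increase | incidental |
| Basic orange 31 | GGT | increase | incidental |
| Disperse violet 1 | cholesterol | increase | not_histopath_supported |
| Disperse violet 1 | triglycerides | increase | not_histopath_supported |

### Qualifier policy for reference counts

The default query policy excludes nothing: counts reflect raw table
presence, so the any-parameter/any-direction screen returns **53** distinct
compounds. The table has **19** non-empty ALT cells; the reference manual
count of **18** ALT-affecting ingredients is reproduced by excluding the
single `non_OECD`-qualified ALT entry (butylphenyl methylpropional) —
consistent with the screen's focus on 90-day guideline studies. That
exclusion is a documented, configurable policy
(`exclude_qualifiers = "non_OECD"`), not hard-coded behaviour.

### Compound metadata

`screening_compounds.csv` carries CAS numbers and SMILES only for compounds
whose identity is unambiguous (Basic Yellow 57, phenoxyethanol, triclosan,
N-methyl-2-pyrrolidone); other identifier cells are deliberately empty
rather than guessed. Polysilicone-15 is flagged `is_polymer` and carries no
SMILES (polymers have no canonical SMILES notation). Use categories are
assigned from the table's function column. `screening_opinions.csv` provides
one synthetic placeholder opinion per compound (`is_placeholder = TRUE`);
opinion numbers and years are NOT real SCCS accession data.

## Corpus category counts (`corpus_categories.csv`)

The seven published use-category totals (62 hair dyes, 9 preservatives and
disinfectants, 5 UV filters, 2 fragrances, 2 solvents, 4 multiple-use, 4
other; 88 ingredients in total). `load_corpus_metadata()` fills each
category up to its total with placeholder-flagged synthetic records beyond
the 53 named screening-table ingredients; placeholders carry no findings.

## Example study records (`screening_studies.csv`)

Two synthetic OECD 408 study records in the linearized CSV dialect
(`path=value` pairs joined with `|`; embedded slashes in property names
escaped as `\/`). The Basic Red 51 record emulates the published 90-day
study content used in the knowledge-graph walkthrough: increased ALP and
GGT in clinical biochemistry and hepatocellular necrosis in histopathology.
It is a synthetic reconstruction for fixture use, not SCCS text.

## Ontology fixture (`mini_ontology.ttl`)

A ~30-node synthetic miniature of the enriched toxic-process ontology:
cholestasis with three contextual adverse effects (increased blood ALP,
presence of GGT, necrosis); NAFLD under lipidosis with two own and two
inherited effects; two pathways; two gene products. Identifiers live under
`example.org` namespaces — this is a stand-in, not a TXPO/GO/UniProt import.

## Other files

* `profiles/` — guideline profiles (OECD 408 repeated-dose, OECD 401 acute).
* `rulebook.yaml` — ToxRTool question catalogue + answer-derivation rules.
* `lexicons/liver_parameters.yaml` — parameter synonym lexicon.
* `effect_token_alignment.csv` — bridges (parameter, direction) findings to
  ontology effect labels.
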