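Package: toxinkg
Title: Guideline-Profiled Toxicology Knowledge Graph for Cosmetic Ingredient Safety Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curates repeated-dose toxicity study data on cosmetic ingredients into a
    guideline-profiled data model (OECD test guideline concept/value-property trees),
    scores study reliability automatically with a ToxRTool-based Klimisch category
    engine, screens structured findings for hepatotoxicity signals through
    parameter-synonym and direction-keyword lexicons, standardizes chemical identity
    (canonical SMILES, CAS checksums, fuzzy name search, Dice-similarity structural
    alerts), and builds an RDF knowledge graph in named graphs with rule-based
    "sameAs" and "is affected by" link inference that answers competency questions
    about adverse effects, toxic processes, pathways, and gene products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    ChemmineOB,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
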