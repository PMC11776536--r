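test_that("quad sets round-trip exactly through TriG and N-Quads", {
  kg <- built_kg()
  tf1 <- withr::local_tempfile(fileext = ".trig")
  write_trig(kg, tf1)
  expect_identical(kg_quads(read_trig(tf1)), kg_quads(kg))
  tf2 <- withr::local_tempfile(fileext = ".nq")
  write_nquads(kg, tf2)
  expect_identical(kg_quads(read_nquads(tf2)), kg_quads(kg))
})

test_that("literals with quotes, backslashes and newlines survive serialization", {
  kg <- kg_new()
  kg <- kg_add(kg, "tx:x", "rdfs:label", "a \"quoted\" \\ line\nnext",
               literal = TRUE)
  tf <- withr::local_tempfile(fileext = ".nq")
  write_nquads(kg, tf)
  expect_identical(kg_quads(read_nquads(tf)), kg_quads(kg))
})

test_that("the Turtle reader parses the ontology fixture structure", {
  onto <- mini_ontology()
  q <- kg_quads(onto)
  expect_true(all(q$graph == "ontology"))
  label <- "http://www.w3.org/2000/01/rdf-schema#label"
  labs <- q[q$predicate == label, ]
  expect_true("increased blood ALP concentration" %in% labs$object)
  # predicate lists (;) and object lists (,) both parsed
  types <- q[q$predicate == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type", ]
  chol <- types[types$subject == "http://example.org/txpo/cholestasis", ]
  expect_equal(nrow(chol), 2)  # Disease and ToxicProcess
})

test_that("dataset-derived quads stay in `internal`; links never leak into it", {
  ds <- load_screening_table()
  kg0 <- build_kg(ds)
  expect_setequal(unique(kg0$quads$graph), "internal")
  kg <- built_kg(ds)
  internal <- kg_quads(kg, "internal")
  expect_false(any(grepl("sameAs", internal$predicate)))
  expect_false(any(grepl("isAffectedBy|sharedEffectCount", internal$predicate)))
  expect_true(kg_size(kg, "external_links") > 0)
  expect_true(kg_size(kg, "inferred") > 0)
  # building twice is deterministic
  expect_identical(kg_quads(build_kg(ds)), kg_quads(kg0))
})

test_that("an empty dataset builds an empty internal graph", {
  dir <- withr::local_tempdir()
  write_mini_csvs(dir, compounds = data.frame(compound_id = character(0),
                                              ingredient_name = character(0)))
  ds <- read_dataset(dir)
  expect_equal(kg_size(build_kg(ds)), 0)
})

test_that("mapping rules produce the expected quads for a one-row-per-kind dataset", {
  dir <- withr::local_tempdir()
  write_mini_csvs(
    dir,
    compounds = data.frame(compound_id = "a", ingredient_name = "Compound A",
                           cas_number = "122-99-6"),
    opinions = data.frame(opinion_id = "OP-1", year = 2015,
                          compound_id = "a"),
    effects = data.frame(compound_id = "a", parameter = "ALP",
                         direction = "increase"))
  ds <- read_dataset(dir)
  kg <- build_kg(ds)
  q <- kg_quads(kg)
  # counted by applying the shipped rules by hand:
  # compound: type, label, cas, useCategory (default "other")   = 4
  # opinion: type, label, aboutCompound, year                   = 4
  # observation: type, label, parameter, direction, hasObservation = 5
  expect_equal(nrow(q), 13)
  # CAS-keyed IRI minting
  expect_true("http://example.org/toxin/compound/cas-122-99-6" %in% q$subject)
  obs_label <- q[q$object == "increased blood ALP concentration", ]
  expect_equal(nrow(obs_label), 1)
})

test_that("rules referencing missing columns raise a mapping error naming the rule", {
  ds <- load_screening_table()
  bad <- list(list(source = "compounds", subject = "{nonexistent}",
                   predicate = "tx:p", object = "ingredient_name",
                   literal = TRUE, constant = FALSE))
  expect_error(build_kg(ds, rules = bad), "missing column")
})

test_that("sameAs links come from normalized label equality, ambiguity warns", {
  kg <- kg_new()
  kg <- kg_add(kg, "tx:obs/1", "rdfs:label", "  Necrosis ", literal = TRUE)
  onto <- kg_new()
  onto <- kg_add(onto, "txo:necrosis", "rdfs:label", "necrosis",
                 graph = "ontology", literal = TRUE)
  linked <- link_same_as(kg, onto)
  ext <- kg_quads(linked, "external_links")
  expect_equal(nrow(ext), 1)
  expect_equal(ext$predicate, "http://www.w3.org/2002/07/owl#sameAs")

  # no shared labels -> no links
  onto2 <- kg_new()
  onto2 <- kg_add(onto2, "txo:x", "rdfs:label", "something else",
                  graph = "ontology", literal = TRUE)
  expect_equal(kg_size(link_same_as(kg, onto2), "external_links"), 0)

  # one internal label matching two ontology entities -> two links + warning
  onto3 <- kg_add(onto, "txo:necrosis2", "rdfs:label", "NECROSIS",
                  graph = "ontology", literal = TRUE)
  expect_warning(linked3 <- link_same_as(kg, onto3), "ambiguous")
  expect_equal(kg_size(linked3, "external_links"), 2)
})

test_that("effect profiles close over is_a inheritance", {
  profiles <- effect_profiles(mini_ontology())
  nafld <- profiles[["http://example.org/txpo/NAFLD"]]
  expect_setequal(nafld$effects, normalize_label(c(
    "increased hepatic triglycerides", "hepatic fat accumulation",
    "hyperfunction of lipid biosynthesis",
    "hyperfunction of cholesterol biosynthesis")))
  chol <- profiles[["http://example.org/txpo/cholestasis"]]
  expect_setequal(chol$effects, normalize_label(c(
    "increased blood ALP concentration", "presence of GGT in blood",
    "necrosis")))
})

test_that("inferred shared counts equal a brute-force intersection oracle", {
  kg <- built_kg(min_shared = 1)
  links <- affected_by_links(kg)
  profiles <- effect_profiles(kg)
  tokens <- toxinkg:::opinion_tokens(kg)
  for (i in seq_len(nrow(links))) {
    oracle <- length(intersect(tokens[[links$subject[i]]],
                               profiles[[links$entity[i]]]$effects))
    expect_identical(links$shared_count[i], as.integer(oracle))
  }
  # and no qualifying pair is missed
  n_expected <- sum(vapply(names(tokens), function(op) {
    sum(vapply(profiles, function(pr) {
      length(intersect(tokens[[op]], pr$effects)) >= 1
    }, logical(1)))
  }, integer(1)))
  expect_equal(nrow(links), n_expected)
})

test_that("the Basic Red 51 opinion links to cholestasis with three shared effects", {
  links <- affected_by_links(built_kg())
  br51 <- links[grepl("basic-red-51", links$subject), ]
  expect_equal(nrow(br51), 1)
  expect_match(br51$entity, "cholestasis")
  expect_equal(br51$shared_count, 3L)
})

test_that("a subject matching only inherited effects still counts them", {
  # dataset whose single compound shows the two lipidosis-level effects
  kg <- kg_new()
  kg <- kg_add(kg, "tx:opinion/test", "rdf:type", "tx:Opinion")
  for (i in 1:2) {
    obs <- paste0("tx:obs/", i)
    kg <- kg_add(kg, "tx:opinion/test", "tx:hasObservation", obs)
    kg <- kg_add(kg, obs, "rdfs:label",
                 c("hyperfunction of lipid biosynthesis",
                   "hyperfunction of cholesterol biosynthesis")[i],
                 literal = TRUE)
  }
  kg <- link_same_as(kg, mini_ontology())
  kg <- infer_affected_by(kg, min_shared = 2)
  links <- affected_by_links(kg)
  nafld <- links[grepl("NAFLD", links$entity), ]
  expect_equal(nafld$shared_count, 2L)   # both inherited from lipidosis
})

test_that("min_shared is monotone: lowering never removes, raising never adds", {
  ds <- load_screening_table()
  l1 <- affected_by_links(built_kg(ds, min_shared = 1))
  l2 <- affected_by_links(built_kg(ds, min_shared = 2))
  l3 <- affected_by_links(built_kg(ds, min_shared = 3))
  key <- function(l) paste(l$subject, l$entity)
  expect_true(all(key(l2) %in% key(l1)))
  expect_true(all(key(l3) %in% key(l2)))
  expect_true(all(l2$shared_count >= 2))
  expect_true(all(l3$shared_count >= 3))
})

test_that("q1 ranks cholestasis first for the walkthrough observation set", {
  kg <- built_kg()
  res <- competency_query(kg, "q1_effects_to_processes", list(
    effects = c("increased blood ALP concentration",
                "presence of GGT in blood", "necrosis")))
  expect_equal(res$label[1], "liver cholestasis")
  expect_equal(res$shared_count[1], 3)
  # ranking is a deterministic total order
  expect_identical(res, competency_query(kg, "q1_effects_to_processes", list(
    effects = c("necrosis", "presence of GGT in blood",
                "increased blood ALP concentration"))))
})

test_that("q2 reaches the fatty acid biosynthetic process from NAFLD", {
  res <- competency_query(built_kg(), "q2_disease_to_pathways",
                          list(disease = "NAFLD"))
  expect_true("fatty acid biosynthetic process" %in% res$label)
})

test_that("q3 returns acetyl-CoA carboxylase 1 for the NAFLD lipid process", {
  res <- competency_query(built_kg(), "q3_process_to_gene_products",
                          list(process = "NAFLD"))
  expect_true("acetyl-CoA carboxylase 1" %in% res$label)
})

test_that("unknown entities yield an empty result with a warning", {
  kg <- built_kg()
  expect_warning(res <- competency_query(kg, "q2_disease_to_pathways",
                                         list(disease = "txo:unobtainium")),
                 "unknown entity")
  expect_equal(nrow(res), 0)
})
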