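test_that("parameter synonyms normalize case-insensitively to canonical tokens", {
  expect_equal(normalize_parameter("SGPT"), "ALT")
  expect_equal(normalize_parameter("serum glutamate-pyruvate transaminase"), "ALT")
  expect_equal(normalize_parameter("alat"), "ALT")
  expect_equal(normalize_parameter("ALT"), "ALT")   # canonical fixed point
  expect_equal(normalize_parameter(c("gpt", "Alkaline Phosphatase")),
               c("ALT", "ALP"))
  expect_true(is.na(normalize_parameter("banana"))) # no-match, not an error
})

test_that("synonym sets are pairwise disjoint in the shipped lexicon", {
  lex <- parameter_lexicon()
  expect_equal(anyDuplicated(names(lex$lookup)), 0)
  expect_equal(unname(lex$ec_numbers["ALT"]), "2.6.1.2")
})

test_that("direction keywords normalize per the synonym groups", {
  expect_equal(normalize_direction("higher"), "increase")
  expect_equal(normalize_direction("raise"), "increase")
  expect_equal(normalize_direction("elevated"), "increase")
  expect_equal(normalize_direction("reduced"), "decrease")
  expect_equal(normalize_direction("altered"), "change")
  expect_equal(normalize_direction("differ"), "change")
  expect_equal(normalize_direction("Increase/decrease"), "mixed")
  expect_equal(normalize_direction("Decrease/increase"), "mixed")
  expect_true(is.na(normalize_direction("sideways")))
})

test_that("the any/any screen returns the 53 screening-table compounds", {
  ds <- load_screening_table()
  hits <- liver_query(ds, parameter = NULL, direction = "any")
  expect_equal(nrow(hits), 53)
  # deterministic ordering by ingredient name
  expect_equal(hits$ingredient_name, sort(hits$ingredient_name))
})

test_that("the ALT screen reproduces the 18-compound reference count", {
  ds <- load_screening_table()
  # raw table presence: 19 ALT rows
  raw <- liver_query(ds, parameter = "ALT", direction = "any")
  expect_equal(nrow(raw), 19)
  # fixture-documented qualifier policy: exclude the non-OECD finding
  hits <- liver_query(ds, parameter = "ALT", direction = "any",
                      exclude_qualifiers = "non_OECD")
  expect_equal(nrow(hits), 18)
  expect_false("Butylphenyl methylpropional" %in% hits$ingredient_name)
})

test_that("synonym substitution in the query never changes the hit set", {
  ds <- load_screening_table()
  for (syn in c("SGPT", "GPT", "ALAT", "alanine aminotransferase")) {
    expect_identical(
      liver_query(ds, parameter = syn, direction = "any",
                  exclude_qualifiers = "non_OECD")$compound_id,
      liver_query(ds, parameter = "ALT", direction = "any",
                  exclude_qualifiers = "non_OECD")$compound_id,
      info = syn)
  }
})

test_that("the pure-increase ALP group has the eight expected members", {
  ds <- load_screening_table()
  hits <- liver_query(ds, parameter = "ALP", direction = "pure_increase")
  expect_equal(nrow(hits), 8)
  expect_true(all(c("Basic Red 51", "Phenoxyethanol") %in%
                    hits$ingredient_name))
  # mixed entries are excluded from pure_increase but matched by increase
  inc <- liver_query(ds, parameter = "ALP", direction = "increase")
  expect_gt(nrow(inc), nrow(hits))
  expect_true("Triclosan" %in% inc$ingredient_name)      # ALP inc/dec
  expect_false("Triclosan" %in% hits$ingredient_name)
})

test_that("direction=any equals the union of the per-direction hit sets", {
  ds <- load_screening_table()
  for (param in list(NULL, "ALT", "cholesterol")) {
    any_hits <- liver_query(ds, parameter = param,
                            direction = "any")$compound_id
    union_ids <- unique(unlist(lapply(
      c("increase", "decrease", "change", "mixed"),
      function(d) liver_query(ds, parameter = param,
                              direction = d)$compound_id)))
    expect_setequal(any_hits, union_ids)
  }
})

test_that("enlarging the exclusion set never adds hits", {
  ds <- load_screening_table()
  flags <- c("non_OECD", "doubtful_or_unrelated", "dermal", "human",
             "incidental")
  prev <- liver_query(ds, parameter = NULL, direction = "any")$compound_id
  for (k in seq_along(flags)) {
    cur <- liver_query(ds, parameter = NULL, direction = "any",
                       exclude_qualifiers = flags[seq_len(k)])$compound_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("every hit's evidence entries satisfy the query predicate", {
  ds <- load_screening_table()
  hits <- liver_query(ds, parameter = "cholesterol", direction = "increase",
                      exclude_qualifiers = "human")
  for (i in seq_len(nrow(hits))) {
    e <- hits$entries[[i]]
    expect_true(all(e$parameter == "cholesterol"))
    expect_true(all(e$direction %in% c("increase", "mixed")))
    expect_false(any(grepl("human", e$qualifiers)))
  }
})

test_that("grouping by shared effect equals the matching query hit set", {
  ds <- load_screening_table()
  grp <- group_by_shared_effect(ds, "ALP", "pure_increase")
  q <- liver_query(ds, parameter = "ALP", direction = "pure_increase")
  expect_identical(grp$compound_id, q$compound_id)
  # a compound with two effects appears in both groups
  alt <- group_by_shared_effect(ds, "ALT", "any")$compound_id
  alp <- group_by_shared_effect(ds, "ALP", "any")$compound_id
  expect_true("phenoxyethanol" %in% intersect(alt, alp))
  # unknown parameter: empty group, no error
  expect_equal(nrow(group_by_shared_effect(ds, "unobtainium", "any")), 0)
})

test_that("an empty dataset yields empty hits", {
  dir <- withr::local_tempdir()
  write_mini_csvs(dir, compounds = data.frame(compound_id = character(0),
                                              ingredient_name = character(0)))
  ds <- read_dataset(dir)
  expect_equal(nrow(liver_query(ds, parameter = NULL, direction = "any")), 0)
})
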