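test_that("the question catalogue matches the ToxRTool checklist structure", {
  q <- toxr_questions()
  expect_equal(nrow(q), 21)
  expect_equal(as.integer(table(q$group)[c("I", "II", "III", "IV", "V")]),
               c(4L, 5L, 7L, 3L, 2L))
  expect_setequal(q$id[q$weight == "red"],
                  c("I.1", "II.1", "III.1", "III.2", "III.3", "III.4",
                    "III.5", "V.1"))
})

test_that("initial category thresholds match the printed rule for every sum", {
  # independent oracle: direct restatement of the printed thresholds
  oracle <- function(s) if (s >= 18) 1L else if (s >= 13) 2L else 3L
  for (s in 0:21) expect_identical(initial_category(s), oracle(s))
  expect_error(initial_category(22), "0..21")
  expect_error(initial_category(-1), "0..21")
  expect_error(initial_category(13.5), "0..21")
})

test_that("category revision agrees with a brute-force oracle over all red patterns", {
  rb <- toxr_rulebook()
  qtab <- toxr_questions(rb)
  red_ids <- qtab$id[qtab$weight == "red"]
  normal_ids <- qtab$id[qtab$weight == "normal"]
  # enumerate all 2^8 red patterns; normal answers chosen to realize a range
  # of sums for each pattern
  patterns <- expand.grid(rep(list(0:1), length(red_ids)))
  for (i in seq_len(nrow(patterns))) {
    red_scores <- as.integer(patterns[i, ])
    for (n_normal in c(0L, 7L, 13L)) {
      scores <- c(red_scores, rep(1L, n_normal),
                  rep(0L, length(normal_ids) - n_normal))
      answers <- data.frame(question_id = c(red_ids, normal_ids),
                            score = scores)
      s <- sum(scores)
      init <- initial_category(s)
      all_red <- all(red_scores == 1L)
      expect_identical(revise_category(answers, init, rb, "three"),
                       if (all_red) init else 3L)
      expect_identical(revise_category(answers, init, rb, "sum_capped_two"),
                       if (all_red) init else max(init, 2L))
    }
  }
})

test_that("III.6 follows the route-dependent administration-scheme rule", {
  p <- oecd408()
  base <- complete_study()

  # gavage lacking homogeneity/stability but with dose-volume present -> 1
  gav <- drop_fields(base, HOMOG_PATH)
  a <- derive_answers(gav, p)
  expect_equal(a$score[a$question_id == "III.6"], 1)

  # gavage lacking both -> 0
  gav0 <- drop_fields(base, c(HOMOG_PATH, DOSEVOL_PATH))
  a <- derive_answers(gav0, p)
  expect_equal(a$score[a$question_id == "III.6"], 0)

  # dietary study lacking homogeneity/stability -> 0 (dose-volume irrelevant)
  diet <- set_field(drop_fields(base, HOMOG_PATH), ROUTE_PATH, "diet")
  a <- derive_answers(diet, p)
  expect_equal(a$score[a$question_id == "III.6"], 0)

  # dietary study with homogeneity and stability -> 1
  diet1 <- set_field(base, ROUTE_PATH, "diet")
  a <- derive_answers(diet1, p)
  expect_equal(a$score[a$question_id == "III.6"], 1)
})

test_that("III.4 accepts the control block or a 0 dose level as negative control", {
  p <- oecd408()
  base <- complete_study()
  base$reliability$control_recovery_group <- NA_character_

  with0 <- set_field(base, "Test method/Test condition/dose levels",
                     "0; 50; 150; 450")
  a <- derive_answers(with0, p)
  expect_equal(a$score[a$question_id == "III.4"], 1)

  no0 <- set_field(base, "Test method/Test condition/dose levels",
                   "50; 150; 450")
  a <- derive_answers(no0, p)
  expect_equal(a$score[a$question_id == "III.4"], 0)

  # control & recovery block present wins regardless of dose levels
  no0$reliability$control_recovery_group <- "control and recovery groups"
  a <- derive_answers(no0, p)
  expect_equal(a$score[a$question_id == "III.4"], 1)
})

test_that("III.3 is satisfied by guideline defaults and flagged as such", {
  p <- oecd408()
  rec <- drop_fields(complete_study(),
                     c("Test method/Test condition/repeated administration scheme",
                       "Test method/Test condition/duration of exposure"))
  a <- derive_answers(rec, p)
  expect_equal(a$score[a$question_id == "III.3"], 1)
  expect_true(a$used_default[a$question_id == "III.3"])
  # with defaults disabled the same question fails
  a2 <- derive_answers(rec, p, use_defaults = FALSE)
  expect_equal(a2$score[a2$question_id == "III.3"], 0)
})

test_that("non-OECD studies are not scorable", {
  rec <- study_record("s1", "c1", "non-OECD")
  expect_error(derive_answers(rec, oecd408()), "OECD-compliant")
})

test_that("a fully specified record scores 21, category 1/1", {
  r <- score_study(complete_study(), oecd408())
  expect_equal(r$sum, 21)
  expect_equal(r$initial_category, 1L)
  expect_equal(r$revised_category, 1L)
})

test_that("a red failure forbids categories 1 and 2 under the default policy", {
  p <- oecd408()
  rec <- drop_fields(complete_study(), "Test animal/species") # II.1 is red
  r <- score_study(rec, p)
  expect_equal(r$sum, 20)
  expect_equal(r$initial_category, 1L)
  expect_equal(r$revised_category, 3L)
  r2 <- score_study(rec, p, red_fail_policy = "sum_capped_two")
  expect_equal(r2$revised_category, 2L)
})

test_that("a 13-evidence record with all reds passing lands in category 2", {
  p <- oecd408()
  # drop exactly 8 normal-question evidence paths, keep every red satisfied
  rec <- drop_fields(complete_study(), c(
    "Test method/Test substance/purity",                  # I.2
    "Test method/Test substance/source or origin",        # I.3
    "Test method/Test substance/physicochemical properties", # I.4
    "Test animal/sex",                                    # II.2
    "Test animal/strain",                                 # II.3
    c("Test animal/age value", "Test animal/body weight"), # II.4
    c("Test animal/housing conditions",
      "Test animal/feeding conditions"),                  # II.5
    "Results/statistical methods"                         # IV.3
  ))
  # III.6 still passes (gavage + homogeneity); III.7 passes
  r <- score_study(rec, p)
  expect_equal(r$sum, 21 - 8)
  expect_equal(r$initial_category, 2L)
  expect_equal(r$revised_category, 2L)
})

test_that("flipping any single answer 0 -> 1 never worsens a category", {
  rb <- toxr_rulebook()
  qtab <- toxr_questions(rb)
  set.seed(11)
  for (rep in 1:25) {
    scores <- sample(0:1, 21, replace = TRUE)
    answers <- data.frame(question_id = qtab$id, score = scores)
    init <- initial_category(sum(scores))
    rev <- revise_category(answers, init, rb)
    zeros <- which(scores == 0L)
    for (j in zeros) {
      s2 <- scores; s2[j] <- 1L
      a2 <- data.frame(question_id = qtab$id, score = s2)
      init2 <- initial_category(sum(s2))
      rev2 <- revise_category(a2, init2, rb)
      expect_lte(init2, init)
      expect_lte(rev2, rev)
    }
  }
})

test_that("defaults only ever add evidence (sum monotonicity) and scoring is deterministic", {
  p <- oecd408()
  set.seed(5)
  recs <- generate_studies(generator_config(seed = 5, n_studies = 8,
                                            completeness = 0.6))
  for (rec in recs) {
    with_d <- score_study(rec, p, use_defaults = TRUE)
    without_d <- score_study(rec, p, use_defaults = FALSE)
    expect_gte(with_d$sum, without_d$sum)
    expect_identical(score_study(rec, p), with_d)
  }
})

test_that("acute studies skip II.5 and III.7 and score over the remaining questions", {
  p401 <- profile_registry()$OECD_401
  g <- generate_studies(generator_config(seed = 3, n_studies = 1,
                                         guideline_mix = c(OECD_401 = 1)))
  a <- derive_answers(g[[1]], p401)
  expect_false(any(c("II.5", "III.7") %in% a$question_id))
  expect_equal(nrow(a), 19)
  r <- score_study(g[[1]], p401)
  expect_equal(r$sum, 19)
  expect_equal(r$initial_category, 1L)
})
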