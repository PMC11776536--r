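# Automated ToxRTool answer derivation and Klimisch category assignment.
#
# The ToxRTool checklist (21 questions in 5 criteria groups) operationalizes
# Klimisch reliability grading. Each question scores 0/1; "red" questions are
# mandatory for categories 1-2. Scoring is restricted to OECD-compliant
# studies: non-OECD designs lack the structured evidence the rulebook
# consults.

#' Load the ToxRTool rulebook
#'
#' The rulebook is data, not code: each question maps to evidence paths and a
#' combinator (`ANY`/`ALL`); three questions (III.3, III.4, III.6) carry
#' documented special derivation rules implemented in [derive_answers()].
#'
#' @param path YAML rulebook; defaults to the shipped one.
#' @return list with element `questions` (list of question descriptors).
#' @export
toxr_rulebook <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.toxinkg_cache$rulebook)) return(.toxinkg_cache$rulebook)
    path <- tkg_file("extdata", "rulebook.yaml")
    rb <- yaml::read_yaml(path)
    stopifnot(length(rb$questions) == 21L)
    .toxinkg_cache$rulebook <- rb
    return(rb)
  }
  yaml::read_yaml(path)
}

#' ToxRTool question catalogue
#'
#' @param rulebook optional rulebook (see [toxr_rulebook()]).
#' @return data frame with one row per question: `id`, `group`, `text`,
#'   `weight` (`"red"`/`"normal"`), `applicability`.
#' @export
toxr_questions <- function(rulebook = toxr_rulebook()) {
  qs <- rulebook$questions
  data.frame(
    id = vapply(qs, `[[`, character(1), "id"),
    group = vapply(qs, `[[`, character(1), "group"),
    text = vapply(qs, `[[`, character(1), "text"),
    weight = vapply(qs, `[[`, character(1), "weight"),
    applicability = vapply(qs, `[[`, character(1), "applicability"),
    stringsAsFactors = FALSE
  )
}

question_applies <- function(q, study_kind) {
  switch(q$applicability,
    all = TRUE,
    repeated_dose = study_kind == "repeated_dose",
    inhalation_or_repeated_dose = study_kind %in% c("repeated_dose", "inhalation"),
    stop("unknown applicability: ", q$applicability)
  )
}

answer_row <- function(id, score, evidence, used_default, note = "") {
  data.frame(question_id = id, score = as.integer(score),
             evidence_paths = paste(evidence, collapse = "; "),
             used_default = used_default, note = note,
             stringsAsFactors = FALSE)
}

# numeric dose levels from a linearized cell like "0; 50; 150; 450"
parse_dose_levels <- function(x) {
  if (!is_present(x)) return(numeric(0))
  toks <- unlist(strsplit(as.character(x), "[;|,]"))
  toks <- gsub("[^0-9.eE+-]", " ", toks)
  vals <- suppressWarnings(as.numeric(trimws(toks)))
  vals[!is.na(vals)]
}

field_present <- function(study, path) is_present(study$fields[[path]])

field_default <- function(study, path) {
  identical(unname(study$provenance[path]), "default")
}

#' Derive ToxRTool answers for an OECD-compliant study
#'
#' One answer per applicable question. Presence-check questions score 1 when
#' the combinator over their evidence paths is satisfied. Special rules:
#' * **III.6** (administration scheme details): if the route is oral gavage,
#'   score 1 iff homogeneity and stability are present OR a dose-volume in
#'   ml/kg bw is present; for diet or drinking water, homogeneity and
#'   stability are required.
#' * **III.4** (controls): score 1 if the reliability block's control &
#'   recovery data are present; otherwise 1 iff the dose levels include a "0"
#'   dose (negative control).
#' * **III.3** (frequency/duration): satisfiable by the profile defaults
#'   (7 days/week, 90 days for OECD 408) when the opinion omits them.
#'
#' @param study a [study_record()] with an OECD guideline id.
#' @param profile the matching [guideline_profile()].
#' @param rulebook see [toxr_rulebook()].
#' @param use_defaults apply the profile's default values before scoring
#'   (answers that rely on them are flagged `used_default`).
#' @return data frame of answers (`question_id`, `score`, `evidence_paths`,
#'   `used_default`, `note`).
#' @export
derive_answers <- function(study, profile, rulebook = toxr_rulebook(),
                           use_defaults = TRUE) {
  stopifnot(inherits(study, "study_record"))
  if (identical(study$guideline_id, "non-OECD")) {
    stop("study ", study$study_id, " is not scorable: the Klimisch scoring ",
         "tool covers OECD-compliant studies only")
  }
  stopifnot(inherits(profile, "guideline_profile"))
  if (use_defaults) study <- apply_defaults(study, profile)
  kind <- profile$study_kind

  rows <- list()
  for (q in rulebook$questions) {
    if (!question_applies(q, kind)) next
    rule <- q$rule %||% "presence"
    if (rule == "administration_scheme") {
      route_path <- "Test method/Test condition/Oral administration/route"
      homog_path <- "Test method/Test substance/homogeneity and stability"
      dosevol_path <- "Test method/Test condition/dose-volume ml\\/kg bw"
      route <- tolower(trimws(as.character(study$fields[[route_path]] %||% "")))
      homog <- field_present(study, homog_path) &&
        identical(toupper(trimws(as.character(study$fields[[homog_path]]))), "YES")
      dosevol <- field_present(study, dosevol_path)
      score <- if (identical(route, "gavage")) {
        homog || dosevol
      } else if (route %in% c("diet", "drinking water")) {
        homog
      } else FALSE
      used <- c(route_path, if (homog) homog_path, if (dosevol) dosevol_path)
      rows[[q$id]] <- answer_row(q$id, score, used, FALSE,
                                 note = paste0("route=", route))
    } else if (rule == "controls") {
      crg <- study$reliability$control_recovery_group
      if (is_present(crg)) {
        rows[[q$id]] <- answer_row(q$id, 1L, "reliability/control group & recovery group",
                                   FALSE, note = "control & recovery block present")
      } else {
        doses <- parse_dose_levels(study$fields[[q$paths[[1]]]])
        has_zero <- any(doses == 0)
        rows[[q$id]] <- answer_row(q$id, has_zero, q$paths[[1]], FALSE,
                                   note = if (has_zero) "0 dose level = negative control"
                                          else "no control evidence")
      }
    } else {
      paths <- if (kind == "acute" && !is.null(q$acute_paths)) {
        unlist(q$acute_paths)
      } else unlist(q$paths)
      present <- vapply(paths, field_present, logical(1), study = study)
      score <- if (identical(q$combinator %||% "ANY", "ALL")) all(present)
               else any(present)
      used <- paths[present]
      used_default <- score && any(vapply(used, field_default, logical(1),
                                          study = study))
      rows[[q$id]] <- answer_row(q$id, score, if (length(used)) used else paths,
                                 used_default)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Initial Klimisch category from the ToxRTool sum
#'
#' A sum of 18 or higher is category 1, 13-17 category 2, below 13 category 3.
#'
#' @param sum integer ToxRTool sum, 0-21.
#' @return integer category 1, 2 or 3.
#' @export
initial_category <- function(sum) {
  if (!is.numeric(sum) || length(sum) != 1L || is.na(sum) ||
      sum != round(sum) || sum < 0 || sum > 21) {
    stop("ToxRTool sum must be an integer in 0..21, got ", deparse(sum))
  }
  if (sum >= 18) 1L else if (sum >= 13) 2L else 3L
}

#' Revise the Klimisch category using the red-question rule
#'
#' Red questions are mandatory for categories 1 and 2: when every applicable
#' red question scores 1, the revised category equals the initial one. When a
#' red question fails, the default policy (`"three"`) assigns category 3 (the
#' study cannot achieve 1 or 2). The alternative reading, under which a red
#' failure yields "category 2 or 3 depending on the sum", is available as
#' `red_fail_policy = "sum_capped_two"` (revised = max(initial, 2)). The two
#' readings are deliberately not reconciled; the policy is explicit.
#'
#' @param answers answer data frame from [derive_answers()].
#' @param initial initial category from [initial_category()].
#' @param rulebook see [toxr_rulebook()].
#' @param red_fail_policy `"three"` (default) or `"sum_capped_two"`.
#' @return integer revised category; never a better (smaller) number than
#'   `initial`.
#' @export
revise_category <- function(answers, initial,
                            rulebook = toxr_rulebook(),
                            red_fail_policy = c("three", "sum_capped_two")) {
  red_fail_policy <- match.arg(red_fail_policy)
  qtab <- toxr_questions(rulebook)
  red_ids <- qtab$id[qtab$weight == "red"]
  red_scores <- answers$score[answers$question_id %in% red_ids]
  if (all(red_scores == 1L)) return(as.integer(initial))
  if (red_fail_policy == "three") 3L else max(as.integer(initial), 2L)
}

#' Score one study: answers, sum, initial and revised category
#'
#' Composition of [derive_answers()], [initial_category()] and
#' [revise_category()]. The result keeps full per-question provenance so
#' paper-sourced evidence can be rendered distinctly from applied defaults.
#'
#' @inheritParams derive_answers
#' @inheritParams revise_category
#' @return an object of class `reliability_result`: list with `study_id`,
#'   `answers`, `sum`, `initial_category`, `revised_category`,
#'   `defaults_applied`.
#' @export
score_study <- function(study, profile, rulebook = toxr_rulebook(),
                        use_defaults = TRUE,
                        red_fail_policy = c("three", "sum_capped_two")) {
  red_fail_policy <- match.arg(red_fail_policy)
  answers <- derive_answers(study, profile, rulebook, use_defaults)
  s <- sum(answers$score)
  init <- initial_category(s)
  rev <- revise_category(answers, init, rulebook, red_fail_policy)
  structure(
    list(study_id = study$study_id, answers = answers, sum = s,
         initial_category = init, revised_category = rev,
         defaults_applied = answers$question_id[answers$used_default]),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability_result>", x$study_id, "\n")
  cat("  sum:", x$sum, " initial:", x$initial_category,
      " revised:", x$revised_category, "\n")
  if (length(x$defaults_applied)) {
    cat("  defaults used for:", paste(x$defaults_applied, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score every OECD study in a dataset
#'
#' @param dataset a `toxin_dataset` (see [read_dataset()]).
#' @param registry profile registry, see [profile_registry()].
#' @inheritParams score_study
#' @return named list of `reliability_result`, keyed by study id; non-OECD
#'   studies are skipped with a message.
#' @export
score_dataset <- function(dataset, registry = profile_registry(),
                          use_defaults = TRUE,
                          red_fail_policy = c("three", "sum_capped_two")) {
  red_fail_policy <- match.arg(red_fail_policy)
  out <- list()
  for (st in dataset$studies) {
    if (identical(st$guideline_id, "non-OECD")) {
      message("skipping non-OECD study ", st$study_id)
      next
    }
    prof <- registry[[st$guideline_id]]
    if (is.null(prof)) {
      message("skipping study ", st$study_id, ": no profile for ",
              st$guideline_id)
      next
    }
    out[[st$study_id]] <- score_study(st, prof, use_defaults = use_defaults,
                                      red_fail_policy = red_fail_policy)
  }
  out
}
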