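# Packaged fixtures and the seeded synthetic study-record generator. The
# fixtures transcribe the published screening table (53 liver toxicants) and
# corpus category counts; the generator produces guideline-conformant
# records at a chosen completeness so reliability-scoring behaviour is
# testable end to end without any real opinion text.

fixture_path <- function(...) tkg_file("extdata", ...)

verify_checksums <- function(files) {
  manifest <- fixture_path("checksums.csv")
  want <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  for (f in files) {
    expected <- want$md5[want$file == f]
    if (length(expected) != 1L) stop("no recorded checksum for fixture ", f)
    got <- unname(tools::md5sum(fixture_path(f)))
    if (!identical(got, expected)) {
      stop("fixture checksum mismatch for ", f,
           " (expected ", expected, ", got ", got, ")")
    }
  }
  invisible(TRUE)
}

#' Load the packaged liver-toxicant screening table
#'
#' The 53-ingredient screening dataset: compounds, one placeholder opinion
#' per compound, the example study records, and one effect entry
#' per non-empty compound x parameter cell with direction and qualifier
#' flags (see the fixture README for the transcription rules). File
#' checksums are verified at load time.
#'
#' @param verify verify fixture checksums (default `TRUE`).
#' @return a `toxin_dataset` with 53 compounds, each with at least one
#'   effect entry.
#' @export
load_screening_table <- function(verify = TRUE) {
  files <- c("screening_compounds.csv", "screening_effects.csv",
             "screening_opinions.csv", "screening_studies.csv")
  if (verify) verify_checksums(files)
  read_dataset(paths = list(
    compounds = fixture_path("screening_compounds.csv"),
    effects = fixture_path("screening_effects.csv"),
    opinions = fixture_path("screening_opinions.csv"),
    studies = fixture_path("screening_studies.csv")
  ))
}

#' Load corpus-level ingredient metadata
#'
#' The seven published use-category counts (totalling 88 ingredients over 93
#' opinions) plus a compound record per ingredient: the 53 named
#' screening-table ingredients and placeholder-flagged synthetic stand-ins
#' for the remainder (placeholders carry no findings and are never presented
#' as real opinion content).
#'
#' @param verify verify fixture checksums (default `TRUE`).
#' @return list with `categories` (data frame `use_category`, `total`,
#'   `named`, `placeholders`) and `compounds` (data frame of 88 records).
#' @export
load_corpus_metadata <- function(verify = TRUE) {
  if (verify) verify_checksums(c("corpus_categories.csv",
                                 "screening_compounds.csv"))
  cats <- utils::read.csv(fixture_path("corpus_categories.csv"),
                          stringsAsFactors = FALSE)
  named <- utils::read.csv(fixture_path("screening_compounds.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  named$is_polymer <- as_logical_col(named$is_polymer)
  named$is_placeholder <- FALSE
  counts <- table(factor(named$use_category, levels = cats$use_category))
  cats$named <- as.integer(counts[cats$use_category])
  cats$placeholders <- cats$total - cats$named
  if (any(cats$placeholders < 0)) {
    stop("named fixture compounds exceed a category total")
  }
  fill <- do.call(rbind, lapply(seq_len(nrow(cats)), function(i) {
    n <- cats$placeholders[i]
    if (n == 0L) return(NULL)
    id <- paste0("placeholder-", slugify(cats$use_category[i]), "-",
                 seq_len(n))
    data.frame(compound_id = id,
               ingredient_name = paste0("Placeholder ingredient (",
                                        cats$use_category[i], ") ",
                                        seq_len(n)),
               inci_name = "", cas_number = "", ec_number = "", smiles = "",
               use_category = cats$use_category[i], is_polymer = FALSE,
               is_placeholder = TRUE, stringsAsFactors = FALSE)
  }))
  compounds <- rbind(named[, names(fill)], fill)
  rownames(compounds) <- NULL
  list(categories = cats, compounds = compounds)
}

# every evidence path the rulebook can consult, with a plausible filled value
complete_field_set <- function(profile) {
  if (profile$study_kind == "acute") {
    duration <- list("Test method/Test condition/observation period" = "14 days")
  } else {
    duration <- list(
      "Test method/Test condition/repeated administration scheme" = "7 days/week",
      "Test method/Test condition/duration of exposure" = "90 days")
  }
  c(list(
    "Test animal/species" = "rat",
    "Test animal/strain" = "Wistar",
    "Test animal/sex" = "male and female",
    "Test animal/age value" = "6",
    "Test animal/age unit" = "weeks",
    "Test animal/body weight" = "180-220 g",
    "Test animal/housing conditions" = "group housed",
    "Test animal/feeding conditions" = "standard diet ad libitum",
    "Test method/Test substance/identification" = "test substance",
    "Test method/Test substance/purity" = "98%",
    "Test method/Test substance/source or origin" = "industry dossier",
    "Test method/Test substance/physicochemical properties" = "solid",
    "Test method/Test substance/homogeneity and stability" = "YES",
    "Test method/Test condition/Oral administration/route" = "gavage",
    "Test method/Test condition/dose levels" = "0; 50; 150; 450",
    "Test method/Test condition/animals per group" = "10",
    "Test method/Test condition/dose-volume ml\\/kg bw" = "10",
    "Results/endpoints and methods" = "clinical biochemistry and histopathology",
    "Results/results description" = "described for all endpoints",
    "Results/statistical methods" = "ANOVA",
    "Results/quantitative results reliability" = "consistent across dose groups",
    "Results/study design appropriateness" = "guideline-conformant"
  ), duration)
}

#' Generator configuration
#'
#' @param seed RNG seed; the same configuration always yields identical
#'   records.
#' @param n_studies number of study records.
#' @param completeness fraction in `[0, 1]` of optional evidence retained;
#'   `1` yields fully specified records that score a ToxRTool sum of 21.
#' @param guideline_mix named weights over guideline ids.
#' @param defect_menu field paths eligible for targeted omission (omitted
#'   from every record, enabling e.g. missing-species red-failure cases).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_studies = 10L, completeness = 1,
                             guideline_mix = c(OECD_408 = 1),
                             defect_menu = character(0)) {
  if (!is.numeric(completeness) || completeness < 0 || completeness > 1) {
    stop("completeness must be a fraction in [0, 1]")
  }
  if (is.null(names(guideline_mix)) || any(guideline_mix < 0)) {
    stop("guideline_mix must be named non-negative weights")
  }
  structure(list(seed = as.integer(seed), n_studies = as.integer(n_studies),
                 completeness = completeness, guideline_mix = guideline_mix,
                 defect_menu = defect_menu),
            class = "generator_config")
}

#' Generate seeded synthetic study records
#'
#' Reproducible records for exercising the reliability engine: at
#' `completeness = 1` every evidence path the rulebook consults is present
#' (sum 21, category 1); lower completeness removes a random subset of
#' non-defect fields; every path on `defect_menu` is always omitted, so
#' targeted cases (missing species -> red II.1 failure -> revised category
#' 3) are constructible.
#'
#' @param cfg a [generator_config()].
#' @param registry profile registry.
#' @return named list of [study_record()]s.
#' @export
generate_studies <- function(cfg, registry = profile_registry()) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  gids <- names(cfg$guideline_mix)
  probs <- cfg$guideline_mix / sum(cfg$guideline_mix)
  out <- list()
  for (i in seq_len(cfg$n_studies)) {
    gid <- sample(gids, 1L, prob = probs)
    profile <- registry[[gid]]
    if (is.null(profile)) stop("no registered profile for ", gid)
    fields <- complete_field_set(profile)
    fields <- fields[!names(fields) %in% cfg$defect_menu]
    if (cfg$completeness < 1) {
      keep <- stats::runif(length(fields)) <= cfg$completeness
      fields <- fields[keep]
    }
    rec <- study_record(
      study_id = sprintf("synthetic-%03d", i),
      compound_id = sprintf("synthetic-compound-%03d", i),
      guideline_id = gid,
      fields = fields,
      reliability = reliability_block(
        study_year = 2000L + (i %% 20L), glp_status = TRUE,
        control_recovery_group = "control and recovery groups included",
        own_comments = "synthetic generated record")
    )
    out[[rec$study_id]] <- rec
  }
  out
}
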