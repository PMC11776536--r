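# CSV ingest: reads the curated CSV intermediary format (one logical record
# per row; embedded tables linearized with ";" between cells and "|" between
# rows) into a validated dataset. Invalid rows are flagged, never dropped:
# the curation ethos keeps discrepancies visible instead of silently fixing
# them.

#' Parse a linearized field map
#'
#' The curated CSV dialect stores a study's concept-path -> value map in one
#' cell: `path=value` pairs joined with `|` (rows), `;` separating cells
#' inside a value. Duplicate paths are preserved at this stage (see
#' [dedupe_redundant_fields()]).
#'
#' @param x character scalar (possibly empty).
#' @return named list of values (names are canonical escaped paths).
#' @export
parse_linear_fields <- function(x) {
  if (!is_present(x)) return(list())
  pairs <- strsplit(x, "|", fixed = TRUE)[[1]]
  out <- list()
  for (p in pairs) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L) stop("malformed field pair (no '='): ", sQuote(p))
    key <- trimws(substr(p, 1, eq - 1L))
    val <- trimws(substr(p, eq + 1L, nchar(p)))
    out <- c(out, setNames(list(val), key))
  }
  out
}

#' Serialize a field map to the linearized dialect
#'
#' @param fields named list of values.
#' @return character scalar.
#' @export
write_linear_fields <- function(fields) {
  if (length(fields) == 0L) return("")
  paste(paste0(names(fields), "=", vapply(fields, as.character, character(1))),
        collapse = "|")
}

#' Collapse redundant repeated fields within study records
#'
#' Opinions repeat dosages, administration routes and test-substance
#' specifications across sections; each datum is captured only once.
#' Identical repeats collapse silently; conflicting repeats are kept (first
#' value wins for the field map) and flagged in the record's `conflicts`
#' table — never silently merged.
#'
#' @param records list of [study_record()]s (or a single record).
#' @return records with unique field names and a `conflicts` data frame
#'   (`path`, `values`) where repeats disagreed.
#' @export
dedupe_redundant_fields <- function(records) {
  single <- inherits(records, "study_record")
  if (single) records <- list(records)
  records <- lapply(records, function(rec) {
    nms <- names(rec$fields)
    if (!anyDuplicated(nms)) return(rec)
    conflicts <- list()
    keep <- list()
    for (p in unique(nms)) {
      vals <- unique(vapply(rec$fields[nms == p], as.character, character(1)))
      keep[[p]] <- vals[[1]]
      if (length(vals) > 1L) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          path = p, values = paste(vals, collapse = " | "),
          stringsAsFactors = FALSE)
      }
    }
    prov <- rec$provenance[unique(nms)]
    rec$fields <- keep
    rec$provenance <- prov
    if (length(conflicts)) rec$conflicts <- do.call(rbind, conflicts)
    rec
  })
  if (single) records[[1]] else records
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("fatal ingest error: unreadable file ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("fatal ingest error: ", basename(path),
         " lacks mandatory columns: ", paste(missing, collapse = ", "))
  }
  df
}

as_logical_col <- function(x) toupper(trimws(x)) %in% c("TRUE", "YES", "1")

chr_or_na <- function(x) {
  x <- x %||% NA_character_
  if (is_present(x)) as.character(x) else NA_character_
}

studies_from_df <- function(df) {
  recs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    rb <- reliability_block(
      sccs_comments = chr_or_na(r$sccs_comments),
      study_year = suppressWarnings(as.integer(chr_or_na(r$study_year))),
      glp_status = if (is_present(r$glp_status)) as_logical_col(r$glp_status) else NA,
      ref_in_dossier = chr_or_na(r$ref_in_dossier),
      additional_information = chr_or_na(r$additional_information),
      own_comments = chr_or_na(r$own_comments),
      control_recovery_group = chr_or_na(r$control_recovery_group)
    )
    rec <- study_record(
      study_id = r$study_id, compound_id = r$compound_id,
      guideline_id = if (is_present(r$guideline_id)) r$guideline_id else "non-OECD",
      fields = parse_linear_fields(r$fields %||% ""),
      reliability = rb,
      opinion_id = chr_or_na(r$opinion_id)
    )
    dedupe_redundant_fields(rec)
  })
  names(recs) <- vapply(recs, `[[`, character(1), "study_id")
  recs
}

#' Read a curated CSV dataset
#'
#' Reads `compounds.csv`, and optionally `opinions.csv`, `studies.csv`,
#' `effects.csv`, from a directory or from explicitly named paths. All rows
#' are parsed; rows failing validation are retained and flagged in the
#' violation report. Record order is canonicalized so row order never affects
#' the resulting dataset.
#'
#' @param data_dir directory containing the CSV files (default names), or
#'   `NULL` when `paths` is given.
#' @param paths named list overriding individual file paths
#'   (`compounds`, `opinions`, `studies`, `effects`).
#' @param registry profile registry for study validation.
#' @return an object of class `toxin_dataset`: list with `compounds`,
#'   `opinions`, `effects` (data frames), `studies` (named list of
#'   [study_record()]) and `violations` (data frame report).
#' @export
read_dataset <- function(data_dir = NULL, paths = list(),
                         registry = profile_registry()) {
  path_of <- function(kind, default) {
    paths[[kind]] %||% if (!is.null(data_dir)) file.path(data_dir, default)
  }
  cpath <- path_of("compounds", "compounds.csv")
  if (is.null(cpath)) stop("fatal ingest error: no compounds file given")
  compounds <- read_csv_checked(cpath, c("compound_id", "ingredient_name"))
  for (col in c("inci_name", "cas_number", "ec_number", "smiles")) {
    if (is.null(compounds[[col]])) compounds[[col]] <- rep("", nrow(compounds))
  }
  if (is.null(compounds$use_category)) {
    compounds$use_category <- rep("other", nrow(compounds))
  }
  compounds$is_polymer <- if (is.null(compounds$is_polymer)) {
    rep(FALSE, nrow(compounds))
  } else as_logical_col(compounds$is_polymer)
  compounds$is_placeholder <- if (is.null(compounds$is_placeholder)) {
    rep(FALSE, nrow(compounds))
  } else as_logical_col(compounds$is_placeholder)
  compounds <- compounds[order(compounds$compound_id), , drop = FALSE]
  rownames(compounds) <- NULL

  violations <- no_violations()
  note <- function(study_id, path, kind, msg) {
    violations <<- rbind(violations, violation(study_id, path, kind, msg))
  }

  # CAS warnings -> violations (legacy numbers are flagged, not fatal)
  with_cas <- nzchar(compounds$cas_number)
  bad_cas <- with_cas & !vapply(compounds$cas_number, function(x) {
    isTRUE(cas_checksum_ok(if (nzchar(x)) x else NA_character_))
  }, logical(1))
  for (i in which(bad_cas)) {
    note(compounds$compound_id[i], "cas_number", "identifier",
         paste0("CAS fails format/checksum: ", compounds$cas_number[i]))
  }

  opinions <- data.frame(opinion_id = character(0), year = integer(0),
                         compound_id = character(0),
                         is_placeholder = logical(0))
  opath <- path_of("opinions", "opinions.csv")
  if (!is.null(opath) && file.exists(opath)) {
    opinions <- read_csv_checked(opath, c("opinion_id", "compound_id"))
    opinions$year <- suppressWarnings(as.integer(opinions$year %||% NA))
    opinions$is_placeholder <- if (is.null(opinions$is_placeholder)) FALSE else
      as_logical_col(opinions$is_placeholder)
    opinions <- opinions[order(opinions$opinion_id, opinions$compound_id), ,
                         drop = FALSE]
    rownames(opinions) <- NULL
    orphans <- setdiff(opinions$compound_id, compounds$compound_id)
    for (o in orphans) {
      note("", "opinions/compound_id", "reference",
           paste0("opinion references unknown compound ", o))
    }
  }

  studies <- list()
  spath <- path_of("studies", "studies.csv")
  if (!is.null(spath) && file.exists(spath)) {
    sdf <- read_csv_checked(spath, c("study_id", "compound_id"))
    # uniqueness of (compound_id, study_id): flagged, rows retained
    key <- paste(sdf$compound_id, sdf$study_id, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      ids <- strsplit(k, "\r", fixed = TRUE)[[1]]
      note(ids[2], "", "uniqueness",
           paste0("duplicated (compound, study) pair: ", ids[1], ", ", ids[2]))
    }
    sdf <- sdf[!duplicated(key), , drop = FALSE]
    sdf <- sdf[order(sdf$study_id), , drop = FALSE]
    studies <- studies_from_df(sdf)
    for (rec in studies) {
      if (!rec$compound_id %in% compounds$compound_id) {
        note(rec$study_id, "compound_id", "reference",
             paste0("study references unknown compound ", rec$compound_id))
      }
      prof <- registry[[rec$guideline_id]]
      violations <- rbind(violations, validate_record(rec, prof))
      if (!is.null(rec$conflicts)) {
        for (j in seq_len(nrow(rec$conflicts))) {
          note(rec$study_id, rec$conflicts$path[j], "conflict",
               paste0("conflicting repeated values: ", rec$conflicts$values[j]))
        }
      }
    }
  }

  effects <- data.frame(compound_id = character(0), parameter = character(0),
                        direction = character(0), qualifiers = character(0),
                        source = character(0), stringsAsFactors = FALSE)
  epath <- path_of("effects", "effects.csv")
  if (!is.null(epath) && file.exists(epath)) {
    effects <- read_csv_checked(epath, c("compound_id", "parameter", "direction"))
    if (is.null(effects$qualifiers)) {
      effects$qualifiers <- rep("", nrow(effects))
    }
    if (is.null(effects$source)) effects$source <- rep("", nrow(effects))
    lex <- parameter_lexicon()
    canon <- normalize_parameter(effects$parameter, lex)
    unknown <- is.na(canon)
    for (i in which(unknown)) {
      note(effects$compound_id[i], "effects/parameter", "lexicon",
           paste0("unknown liver parameter: ", effects$parameter[i]))
    }
    effects$parameter[!unknown] <- canon[!unknown]
    bad_dir <- !effects$direction %in% DIRECTIONS
    for (i in which(bad_dir)) {
      nd <- normalize_direction(effects$direction[i])
      if (!is.na(nd)) {
        effects$direction[i] <- nd
      } else {
        note(effects$compound_id[i], "effects/direction", "lexicon",
             paste0("unknown direction: ", effects$direction[i]))
      }
    }
    effects <- effects[order(effects$compound_id, effects$parameter,
                             effects$direction), , drop = FALSE]
    rownames(effects) <- NULL
  }

  structure(
    list(compounds = compounds, opinions = opinions, studies = studies,
         effects = effects, violations = violations),
    class = "toxin_dataset"
  )
}

#' @export
print.toxin_dataset <- function(x, ...) {
  cat("<toxin_dataset>", nrow(x$compounds), "compounds,",
      nrow(x$opinions), "opinions,", length(x$studies), "studies,",
      nrow(x$effects), "effect entries;", nrow(x$violations), "violations\n")
  invisible(x)
}

#' Write a dataset back to canonical CSV
#'
#' Canonical column order and row order: ingest -> write-back -> re-ingest
#' round-trips to an identical dataset.
#'
#' @param dataset a `toxin_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$compounds, file.path(dir, "compounds.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dataset$opinions, file.path(dir, "opinions.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dataset$effects, file.path(dir, "effects.csv"),
                   row.names = FALSE, na = "")
  sdf <- do.call(rbind, lapply(dataset$studies, function(rec) {
    rb <- rec$reliability
    data.frame(study_id = rec$study_id, compound_id = rec$compound_id,
               opinion_id = rec$opinion_id %||% NA_character_,
               guideline_id = rec$guideline_id,
               fields = write_linear_fields(rec$fields),
               sccs_comments = rb$sccs_comments,
               study_year = rb$study_year, glp_status = rb$glp_status,
               ref_in_dossier = rb$ref_in_dossier,
               additional_information = rb$additional_information,
               own_comments = rb$own_comments,
               control_recovery_group = rb$control_recovery_group,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sdf)) {
    sdf <- data.frame(study_id = character(0), compound_id = character(0))
  }
  utils::write.csv(sdf, file.path(dir, "studies.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

#' Curation accuracy percentage
#'
#' Accuracy of manual data input measured against the source opinions:
#' correct entries x 100 / total entries, rounded to the nearest integer
#' percent (half up).
#'
#' @param correct number of correct entries.
#' @param total total entries reviewed; must be positive.
#' @return integer percentage.
#' @export
curation_accuracy <- function(correct, total) {
  if (length(total) != 1L || !is.finite(total) || total <= 0) {
    stop("undefined metric: total entries must be positive")
  }
  if (correct < 0 || correct > total) {
    stop("correct entries must lie in [0, total]")
  }
  as.integer(floor(correct * 100 / total + 0.5))
}

#' Write a violation report as JSON lines
#'
#' One JSON object per violation: `{study_id, path, kind, message}`.
#'
#' @param violations violation data frame (see [read_dataset()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_violations <- function(violations, path) {
  lines <- vapply(seq_len(nrow(violations)), function(i) {
    jsonlite::toJSON(as.list(violations[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
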