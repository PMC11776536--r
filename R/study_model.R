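# Guideline-profiled domain model: OECD test guidelines are decomposed into a
# tree of "concepts" (structural nodes, capitalized) and "value properties"
# (typed data fields, lowercase). Study records store slash-delimited
# concept-path -> value maps validated against a profile.

VALUE_TYPES <- c("boolean", "numeric", "text", "enum")

#' Create a value property
#'
#' A value property is a typed leaf of a guideline profile. Names are lowercase
#' by convention (concepts are capitalized); boolean properties admit exactly
#' `YES`/`NO`.
#'
#' @param name lowercase property name, e.g. `"dose levels"`.
#' @param value_type one of `"boolean"`, `"numeric"`, `"text"`, `"enum"`.
#' @param unit measurement unit, e.g. `"ml/kg bw"`, or `""`.
#' @param allowed_values allowed values for `enum`; fixed to `YES`/`NO` for
#'   `boolean`.
#' @return an object of class `value_property`.
#' @export
value_property <- function(name, value_type = "text", unit = "",
                           allowed_values = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (name != tolower(name)) {
    stop("value property names are lowercase by convention: ", sQuote(name))
  }
  value_type <- match.arg(value_type, VALUE_TYPES)
  if (value_type == "boolean") {
    if (!is.null(allowed_values) && !setequal(allowed_values, c("YES", "NO"))) {
      stop("boolean properties admit exactly YES/NO")
    }
    allowed_values <- c("YES", "NO")
  }
  if (value_type == "enum" && length(allowed_values) == 0L) {
    stop("enum property ", sQuote(name), " needs allowed_values")
  }
  structure(
    list(name = name, value_type = value_type, unit = unit %||% "",
         allowed_values = allowed_values),
    class = "value_property"
  )
}

#' Create a concept node
#'
#' Concepts shape the data hierarchy and carry no values themselves. Names
#' start with a capital letter; the tree is at most three concept levels deep
#' and sibling names are unique.
#'
#' @param name capitalized concept name, e.g. `"Test condition"`.
#' @param level depth in the profile tree (1-3).
#' @param children list of child `concept_node`s.
#' @param value_properties list of `value_property`s attached to this concept.
#' @return an object of class `concept_node`.
#' @export
concept_node <- function(name, level = 1L, children = list(),
                         value_properties = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (substr(name, 1, 1) != toupper(substr(name, 1, 1))) {
    stop("concept names start with a capital letter: ", sQuote(name))
  }
  if (level > 3L) stop("concept tree is limited to three levels: ", sQuote(name))
  kid_names <- vapply(children, function(k) k$name, character(1))
  if (anyDuplicated(kid_names)) {
    stop("duplicate sibling concepts under ", sQuote(name), ": ",
         paste(kid_names[duplicated(kid_names)], collapse = ", "))
  }
  prop_names <- vapply(value_properties, function(p) p$name, character(1))
  if (anyDuplicated(prop_names)) {
    stop("duplicate value properties under ", sQuote(name))
  }
  structure(
    list(name = name, level = as.integer(level), children = children,
         value_properties = value_properties),
    class = "concept_node"
  )
}

#' Create a guideline profile
#'
#' @param guideline_id e.g. `"OECD_408"`.
#' @param endpoint endpoint description, e.g. `"repeated-dose oral toxicity"`.
#' @param root_concepts list of level-1 `concept_node`s.
#' @param defaults named list mapping canonical paths to default values assumed
#'   for guideline-conformant studies (e.g. duration of exposure `"90 days"`).
#' @param study_kind `"repeated_dose"`, `"acute"` or `"inhalation"`; drives
#'   ToxRTool question applicability.
#' @return an object of class `guideline_profile`.
#' @export
guideline_profile <- function(guideline_id, endpoint, root_concepts,
                              defaults = list(), study_kind = "repeated_dose") {
  stopifnot(is.character(guideline_id), length(guideline_id) == 1L)
  root_names <- vapply(root_concepts, function(k) k$name, character(1))
  if (anyDuplicated(root_names)) stop("duplicate root concepts")
  prof <- structure(
    list(guideline_id = guideline_id, endpoint = endpoint,
         root_concepts = root_concepts, defaults = defaults,
         study_kind = match.arg(study_kind,
                                c("repeated_dose", "acute", "inhalation"))),
    class = "guideline_profile"
  )
  # every declared default must resolve to a value property
  for (p in names(defaults)) {
    node <- resolve_path(prof, p)
    if (!inherits(node, "value_property")) {
      stop("default path ", sQuote(p), " does not name a value property")
    }
  }
  prof
}

#' @export
print.guideline_profile <- function(x, ...) {
  cat("<guideline_profile>", x$guideline_id, "-", x$endpoint, "\n")
  cat("  root concepts:",
      paste(vapply(x$root_concepts, `[[`, character(1), "name"),
            collapse = ", "), "\n")
  cat("  defaults:", length(x$defaults), " study kind:", x$study_kind, "\n")
  invisible(x)
}

#' Resolve a slash-delimited path against a guideline profile
#'
#' Resolution walks the concept tree segment by segment. Stored canonical names
#' are matched case-insensitively against input, but the returned node carries
#' the canonical spelling. Slashes inside property names (`"dose-volume ml/kg
#' bw"`) are escaped as `\/` in serialized paths; [split_path()] handles this.
#'
#' @param profile a `guideline_profile`.
#' @param path slash-delimited path, concepts then (finally) a value property,
#'   or a bare concept path.
#' @return the matching `value_property` or `concept_node`.
#' @export
resolve_path <- function(profile, path) {
  stopifnot(inherits(profile, "guideline_profile"))
  segs <- split_path(path)
  if (length(segs) == 0L) stop("empty path")
  # virtual root holding the root concepts
  current <- list(name = "<root>", children = profile$root_concepts,
                  value_properties = list())
  walked <- character(0)
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    kid_names <- vapply(current$children, `[[`, character(1), "name")
    prop_names <- vapply(current$value_properties, `[[`, character(1), "name")
    k <- match(tolower(seg), tolower(kid_names))
    if (!is.na(k)) {
      current <- current$children[[k]]
      walked <- c(walked, current$name)
      next
    }
    p <- match(tolower(seg), tolower(prop_names))
    if (!is.na(p)) {
      if (i != length(segs)) {
        stop("path continues past value property ", sQuote(seg))
      }
      return(current$value_properties[[p]])
    }
    candidates <- c(kid_names, prop_names)
    stop("cannot resolve segment ", sQuote(seg),
         if (length(walked)) paste0(" under ", sQuote(join_path(walked))),
         "; candidates: ", paste(sQuote(candidates), collapse = ", "))
  }
  current
}

# ---- reliability block & study records --------------------------------------

#' Create a reliability block
#'
#' Carries study-credibility metadata (SCCS comments, study year, GLP status,
#' dossier reference, control & recovery group data). All fields are optional;
#' `own_comments` documents curator observations and never participates in
#' scoring.
#'
#' @param sccs_comments,ref_in_dossier,additional_information,own_comments,control_recovery_group
#'   free-text fields (`NA` when absent).
#' @param study_year integer year or `NA`.
#' @param glp_status `TRUE`/`FALSE` or `NA`.
#' @return an object of class `reliability_block`.
#' @export
reliability_block <- function(sccs_comments = NA_character_,
                              study_year = NA_integer_,
                              glp_status = NA,
                              ref_in_dossier = NA_character_,
                              additional_information = NA_character_,
                              own_comments = NA_character_,
                              control_recovery_group = NA_character_) {
  structure(
    list(sccs_comments = sccs_comments,
         study_year = if (is.na(study_year)) NA_integer_ else as.integer(study_year),
         glp_status = glp_status,
         ref_in_dossier = ref_in_dossier,
         additional_information = additional_information,
         own_comments = own_comments,
         control_recovery_group = control_recovery_group),
    class = "reliability_block"
  )
}

#' Create a study record
#'
#' @param study_id,compound_id identifiers.
#' @param guideline_id a registered guideline id (e.g. `"OECD_408"`) or
#'   `"non-OECD"`.
#' @param fields named list mapping canonical paths to values. Duplicate names
#'   are permitted at construction (raw ingest state); see
#'   [dedupe_redundant_fields()].
#' @param provenance named character vector path -> one of `"paper"`,
#'   `"default"`, `"expert"`; unnamed fields default to `"paper"`.
#' @param reliability a [reliability_block()].
#' @param opinion_id optional SCCS opinion identifier.
#' @return an object of class `study_record`.
#' @export
study_record <- function(study_id, compound_id, guideline_id = "non-OECD",
                         fields = list(), provenance = character(0),
                         reliability = reliability_block(),
                         opinion_id = NA_character_) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  prov <- setNames(rep("paper", length(fields)), names(fields))
  prov[names(provenance)] <- provenance
  structure(
    list(study_id = study_id, compound_id = compound_id,
         guideline_id = guideline_id, fields = fields, provenance = prov,
         reliability = reliability, opinion_id = opinion_id,
         conflicts = NULL),
    class = "study_record"
  )
}

#' @export
print.study_record <- function(x, ...) {
  cat("<study_record>", x$study_id, "compound:", x$compound_id,
      "guideline:", x$guideline_id, "fields:", length(x$fields), "\n")
  invisible(x)
}

USE_CATEGORIES <- c("hair dye", "preservative/disinfectant", "UV filter",
                    "fragrance", "solvent", "multiple", "other")

#' Create a compound record
#'
#' @param ingredient_name ingredient name as printed in the source.
#' @param inci_name,cas_number,ec_number,smiles optional identifiers.
#' @param use_category one of the cosmetic use categories (`"hair dye"`,
#'   `"preservative/disinfectant"`, `"UV filter"`, `"fragrance"`, `"solvent"`,
#'   `"multiple"`, `"other"`).
#' @param is_polymer polymers are unsuitable for canonical SMILES notation and
#'   must not carry one.
#' @param is_placeholder marks synthetic stand-in records (corpus counts only,
#'   no findings).
#' @param compound_id stable identifier; defaults to a slug of the name.
#' @return an object of class `compound_record`.
#' @export
compound_record <- function(ingredient_name, inci_name = NA_character_,
                            cas_number = NA_character_, ec_number = NA_character_,
                            smiles = NA_character_, use_category = "other",
                            is_polymer = FALSE, is_placeholder = FALSE,
                            compound_id = NULL) {
  use_category <- match.arg(use_category, USE_CATEGORIES)
  if (!is.na(cas_number) && !cas_checksum_ok(cas_number)) {
    warning("CAS number fails format/checksum: ", cas_number)
  }
  canonical <- NA_character_
  if (isTRUE(is_polymer) && is_present(smiles)) {
    stop("polymer compounds cannot carry a (canonical) SMILES")
  }
  structure(
    list(compound_id = compound_id %||% slugify(ingredient_name),
         ingredient_name = ingredient_name, inci_name = inci_name,
         cas_number = cas_number, ec_number = ec_number, smiles = smiles,
         canonical_smiles = canonical, use_category = use_category,
         is_polymer = isTRUE(is_polymer),
         is_placeholder = isTRUE(is_placeholder)),
    class = "compound_record"
  )
}

# ---- validation -------------------------------------------------------------

violation <- function(study_id, path, kind, message) {
  data.frame(study_id = study_id, path = path, kind = kind, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(study_id = character(0), path = character(0), kind = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

check_value_type <- function(vp, value) {
  v <- trimws(as.character(value))
  switch(vp$value_type,
    boolean = if (!v %in% c("YES", "NO")) {
      paste0("expected YES/NO, got ", sQuote(v))
    },
    enum = if (!tolower(v) %in% tolower(vp$allowed_values)) {
      paste0("value ", sQuote(v), " not in {",
             paste(vp$allowed_values, collapse = ", "), "}")
    },
    numeric = if (is.na(suppressWarnings(as.numeric(v)))) {
      paste0("expected numeric, got ", sQuote(v))
    },
    text = NULL
  )
}

#' Validate a study record against its guideline profile
#'
#' Pure function: violations are returned as rows, never raised. Every field
#' path must resolve to a declared value property and every value must match
#' its declared type / allowed values. Records with `guideline_id = "non-OECD"`
#' are checked only for type coherence of the generic reliability block.
#'
#' @param record a [study_record()].
#' @param profile the matching [guideline_profile()], or `NULL` for non-OECD.
#' @return a data frame of violations (`study_id`, `path`, `kind`, `message`);
#'   zero rows when the record is clean.
#' @export
validate_record <- function(record, profile = NULL) {
  stopifnot(inherits(record, "study_record"))
  out <- no_violations()
  rb <- record$reliability
  if (!is.na(rb$study_year) && (rb$study_year < 1900 || rb$study_year > 2100)) {
    out <- rbind(out, violation(record$study_id, "reliability/study year",
                                "type", "implausible study year"))
  }
  if (!is.na(rb$glp_status) && !is.logical(rb$glp_status)) {
    out <- rbind(out, violation(record$study_id, "reliability/glp status",
                                "type", "GLP status must be logical"))
  }
  if (identical(record$guideline_id, "non-OECD")) return(out)
  if (is.null(profile)) {
    return(rbind(out, violation(record$study_id, "", "profile",
                                paste0("no profile registered for ",
                                       record$guideline_id))))
  }
  for (p in names(record$fields)) {
    node <- tryCatch(resolve_path(profile, p), error = function(e) e)
    if (inherits(node, "error")) {
      out <- rbind(out, violation(record$study_id, p, "path",
                                  conditionMessage(node)))
    } else if (!inherits(node, "value_property")) {
      out <- rbind(out, violation(record$study_id, p, "path",
                                  "path names a concept, not a value property"))
    } else {
      msg <- check_value_type(node, record$fields[[p]])
      if (!is.null(msg)) {
        out <- rbind(out, violation(record$study_id, p, "type", msg))
      }
    }
  }
  out
}

# ---- profile (de)serialization and registry ---------------------------------

node_to_list <- function(node) {
  out <- list(name = node$name)
  if (length(node$children)) out$concepts <- lapply(node$children, node_to_list)
  if (length(node$value_properties)) {
    out$properties <- lapply(node$value_properties, function(p) {
      pl <- list(name = p$name, value_type = p$value_type)
      if (nzchar(p$unit)) pl$unit <- p$unit
      if (p$value_type == "enum") pl$allowed_values <- p$allowed_values
      pl
    })
  }
  out
}

list_to_node <- function(x, level) {
  concept_node(
    name = x$name, level = level,
    children = lapply(x$concepts %||% list(), list_to_node, level = level + 1L),
    value_properties = lapply(x$properties %||% list(), function(p) {
      value_property(p$name, p$value_type %||% "text", p$unit %||% "",
                     p$allowed_values)
    })
  )
}

#' Write a guideline profile to a YAML file
#'
#' @param profile a `guideline_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  x <- list(guideline_id = profile$guideline_id, endpoint = profile$endpoint,
            study_kind = profile$study_kind,
            concepts = lapply(profile$root_concepts, node_to_list),
            defaults = profile$defaults)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a guideline profile from a YAML file
#'
#' Profiles ship as data files (one per guideline) so new endpoints are
#' additive; see `inst/extdata/profiles/`. Every declared default is resolved
#' at load time.
#'
#' @param path YAML file path.
#' @return a `guideline_profile`.
#' @export
read_profile <- function(path) {
  x <- yaml::read_yaml(path)
  guideline_profile(
    guideline_id = x$guideline_id, endpoint = x$endpoint,
    root_concepts = lapply(x$concepts, list_to_node, level = 1L),
    defaults = x$defaults %||% list(),
    study_kind = x$study_kind %||% "repeated_dose"
  )
}

#' Registry of shipped guideline profiles
#'
#' Loads (and caches) the profile data files shipped with the package:
#' OECD 408 (90-day repeated-dose oral toxicity) and OECD 401 (acute oral
#' toxicity). User profiles can be added via `extra_dirs`.
#'
#' @param extra_dirs additional directories of profile YAML files.
#' @return named list of `guideline_profile` objects keyed by guideline id.
#' @export
profile_registry <- function(extra_dirs = character(0)) {
  key <- paste0("profiles::", paste(extra_dirs, collapse = ";"))
  if (!is.null(.toxinkg_cache[[key]])) return(.toxinkg_cache[[key]])
  dirs <- c(tkg_file("extdata", "profiles"), extra_dirs)
  files <- unlist(lapply(dirs, list.files, pattern = "\\.ya?ml$",
                         full.names = TRUE))
  profs <- lapply(files, read_profile)
  names(profs) <- vapply(profs, `[[`, character(1), "guideline_id")
  .toxinkg_cache[[key]] <- profs
  profs
}

#' Apply a profile's default values to a study record
#'
#' Missing scheme fields of guideline-conformant studies are assumed
#' unintentional omissions, not non-compliance; defaults (e.g. repeated
#' administration scheme "7 days/week", duration of exposure "90 days" for
#' OECD 408) fill them with provenance `"default"`.
#'
#' @param record a `study_record`.
#' @param profile its `guideline_profile`.
#' @return the record with defaults applied and tagged.
#' @export
apply_defaults <- function(record, profile) {
  for (p in names(profile$defaults)) {
    if (!is_present(record$fields[[p]])) {
      record$fields[[p]] <- profile$defaults[[p]]
      record$provenance[[p]] <- "default"
    }
  }
  record
}
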