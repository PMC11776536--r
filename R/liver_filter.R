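# Liver-toxicant screening over structured findings. Opinions name the same
# serum marker many ways (ALT = SGPT = GPT = ALAT = alanine aminotransferase)
# and describe shifts with many verbs (increase/raise/higher ...); the filter
# normalizes both through data-file lexicons before matching, so a query for
# any synonym returns the same hit set as its canonical form.

QUALIFIER_FLAGS <- c("doubtful_or_unrelated", "not_histopath_supported",
                     "incidental", "dermal", "human", "method_interference",
                     "sccs_conclusion_only", "adaptive_compensatory",
                     "non_OECD", "inhalation")

DIRECTIONS <- c("increase", "decrease", "change", "mixed")

#' Load the liver-parameter lexicon
#'
#' @param path YAML lexicon file; defaults to the shipped one. Synonym sets
#'   must be pairwise disjoint across canonical parameters.
#' @return an object of class `parameter_lexicon`: list with `canonical`
#'   (character vector), `ec_numbers`, and `lookup` (named vector synonym ->
#'   canonical, lowercased keys).
#' @export
parameter_lexicon <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache && !is.null(.toxinkg_cache$lexicon)) {
    return(.toxinkg_cache$lexicon)
  }
  if (is.null(path)) path <- tkg_file("extdata", "lexicons", "liver_parameters.yaml")
  raw <- yaml::read_yaml(path)$parameters
  canon <- vapply(raw, `[[`, character(1), "canonical")
  lookup <- character(0)
  for (p in raw) {
    keys <- tolower(c(p$canonical, unlist(p$synonyms)))
    if (any(keys %in% names(lookup))) {
      stop("synonym sets are not pairwise disjoint: ",
           paste(intersect(keys, names(lookup)), collapse = ", "))
    }
    lookup[keys] <- p$canonical
  }
  lex <- structure(
    list(canonical = canon,
         ec_numbers = setNames(vapply(raw, function(p) p$ec_number %||% "",
                                      character(1)), canon),
         lookup = lookup),
    class = "parameter_lexicon"
  )
  if (use_cache) .toxinkg_cache$lexicon <- lex
  lex
}

#' Normalize a parameter term to its canonical token
#'
#' @param term character vector of parameter names or synonyms (any case).
#' @param lexicon a [parameter_lexicon()].
#' @return canonical tokens; `NA` marks unknown terms (not an error).
#' @export
normalize_parameter <- function(term, lexicon = parameter_lexicon()) {
  unname(lexicon$lookup[tolower(trimws(term))])
}

DIRECTION_SYNONYMS <- list(
  increase = c("increase", "increased", "increasing", "raise", "raised",
               "higher", "elevated", "elevation"),
  decrease = c("decrease", "decreased", "lower", "lowered", "reduced",
               "reduction"),
  change = c("change", "changed", "differ", "different", "alter", "altered")
)

#' Normalize a direction keyword
#'
#' `increase`/`raise`/`higher`/`elevated` are synonymous, as are
#' `decrease`/`lower`/`reduced` and `change`/`differ`/`alter`. Compound tokens
#' containing both an increase and a decrease verb (printed as
#' "Increase/decrease") normalize to `"mixed"`.
#'
#' @param term character vector of direction keywords.
#' @return one of `"increase"`, `"decrease"`, `"change"`, `"mixed"`, or `NA`
#'   for unknown terms.
#' @export
normalize_direction <- function(term) {
  one <- function(x) {
    x <- tolower(trimws(x))
    if (!nzchar(x)) return(NA_character_)
    parts <- trimws(unlist(strsplit(x, "/")))
    dir_of <- function(p) {
      hit <- names(DIRECTION_SYNONYMS)[vapply(DIRECTION_SYNONYMS,
                                              function(s) p %in% s, logical(1))]
      if (length(hit)) hit[[1]] else NA_character_
    }
    dirs <- unique(stats::na.omit(vapply(parts, dir_of, character(1))))
    if (length(dirs) == 0L) NA_character_
    else if (all(c("increase", "decrease") %in% dirs)) "mixed"
    else dirs[[1]]
  }
  vapply(term, one, character(1), USE.NAMES = FALSE)
}

#' Construct a liver-filter query
#'
#' @param parameter canonical parameter, any synonym, or `NULL` for "any liver
#'   parameter".
#' @param direction `"increase"`, `"decrease"`, `"change"`, `"mixed"`,
#'   `"any"`, or `"pure_increase"`. A plain `"increase"`/`"decrease"` also
#'   matches `mixed` entries (which encode both); `"pure_increase"` excludes
#'   them.
#' @param exclude_qualifiers qualifier flags whose entries are dropped before
#'   matching (default: none, counts reflect raw table presence).
#' @param lexicon a [parameter_lexicon()].
#' @return an object of class `filter_query`.
#' @export
filter_query <- function(parameter = NULL, direction = "any",
                         exclude_qualifiers = character(0),
                         lexicon = parameter_lexicon()) {
  direction <- match.arg(direction,
                         c("any", "pure_increase", DIRECTIONS))
  if (!is.null(parameter)) {
    canon <- normalize_parameter(parameter, lexicon)
    if (is.na(canon)) {
      canon <- parameter  # unknown term: matches nothing, not an error
    }
    parameter <- canon
  }
  bad <- setdiff(exclude_qualifiers, QUALIFIER_FLAGS)
  if (length(bad)) stop("unknown qualifier flags: ", paste(bad, collapse = ", "))
  structure(list(parameter = parameter, direction = direction,
                 exclude_qualifiers = exclude_qualifiers),
            class = "filter_query")
}

split_qualifiers <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

entry_matches <- function(entry, q) {
  if (!is.null(q$parameter) && entry$parameter != q$parameter) return(FALSE)
  dir_ok <- switch(q$direction,
    any = TRUE,
    pure_increase = entry$direction == "increase",
    increase = entry$direction %in% c("increase", "mixed"),
    decrease = entry$direction %in% c("decrease", "mixed"),
    entry$direction == q$direction
  )
  if (!dir_ok) return(FALSE)
  quals <- split_qualifiers(entry$qualifiers)
  !any(quals %in% q$exclude_qualifiers)
}

#' Query a dataset for compounds with matching liver findings
#'
#' Returns the distinct compounds with at least one effect entry matching the
#' query after qualifier exclusion, ordered deterministically by ingredient
#' name. Each hit lists every matching entry as evidence.
#'
#' @param dataset a `toxin_dataset` (see [read_dataset()]); its `effects`
#'   table holds one row per compound x parameter finding.
#' @param q a [filter_query()] (or arguments to build one via `...`).
#' @param ... passed to [filter_query()] when `q` is missing.
#' @return data frame of hits: `compound_id`, `ingredient_name`, `n_entries`,
#'   plus a list-column `entries` with the matched evidence rows.
#' @export
liver_query <- function(dataset, q = NULL, ...) {
  if (is.null(q)) q <- filter_query(...)
  stopifnot(inherits(q, "filter_query"))
  eff <- dataset$effects
  if (is.null(eff) || nrow(eff) == 0L) {
    return(data.frame(compound_id = character(0),
                      ingredient_name = character(0),
                      n_entries = integer(0)))
  }
  keep <- vapply(seq_len(nrow(eff)),
                 function(i) entry_matches(eff[i, ], q), logical(1))
  hits <- eff[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(compound_id = character(0),
                      ingredient_name = character(0),
                      n_entries = integer(0)))
  }
  name_of <- setNames(dataset$compounds$ingredient_name,
                      dataset$compounds$compound_id)
  ids <- unique(hits$compound_id)
  out <- data.frame(
    compound_id = ids,
    ingredient_name = unname(name_of[ids]),
    n_entries = vapply(ids, function(i) sum(hits$compound_id == i), integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ingredient_name, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out$entries <- lapply(out$compound_id, function(i) {
    e <- hits[hits$compound_id == i, , drop = FALSE]
    rownames(e) <- NULL
    e
  })
  out
}

#' Group compounds sharing a (parameter, direction) effect
#'
#' Partition-style grouping: group membership equals the hit set of the
#' corresponding query, supporting structure-activity comparison of compounds
#' with a common finding.
#'
#' @inheritParams liver_query
#' @param parameter canonical parameter or synonym.
#' @param direction direction enum as in [filter_query()].
#' @param exclude_qualifiers qualifier flags to drop.
#' @return data frame with the group members (same shape as [liver_query()]).
#' @export
group_by_shared_effect <- function(dataset, parameter, direction,
                                   exclude_qualifiers = character(0)) {
  liver_query(dataset, filter_query(parameter = parameter,
                                    direction = direction,
                                    exclude_qualifiers = exclude_qualifiers))
}
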