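# Chemical identity services: canonical SMILES (delegated to Open Babel via
# ChemmineOB, wrapped behind a stable contract), CAS checksum validation,
# fuzzy ingredient-name search, and Dice-similarity structural-alert
# assignment over discrete fingerprint feature sets. The Dice computation is
# plain set algebra implemented here, so the >= 0.5 alert threshold rule is
# testable with synthetic feature sets independent of any chemistry engine.

#' Canonicalize a SMILES string
#'
#' Two SMILES of the same molecule map to one canonical string; the operation
#' is idempotent. Polymers (flagged upstream on the compound record) are not
#' representable and are rejected.
#'
#' @param smiles a parseable SMILES string.
#' @param is_polymer reject with an unsupported-structure error when `TRUE`.
#' @return the canonical SMILES string.
#' @export
canonicalize_smiles <- function(smiles, is_polymer = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (isTRUE(is_polymer)) {
    stop("unsupported structure: polymers have no canonical SMILES notation")
  }
  out <- suppressWarnings(
    tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
             error = function(e) "")
  )
  out <- trimws(out)
  if (!nzchar(out)) stop("SMILES parse error: ", sQuote(smiles))
  out
}

#' Structural fingerprint as a discrete feature set
#'
#' Hashed path-based fragment fingerprint (Open Babel FP2) reduced to the set
#' of on-bit indices. Set semantics (no multiplicity) feed the Dice measure.
#'
#' @param smiles a parseable SMILES string.
#' @return integer vector of distinct feature keys, sorted.
#' @export
fingerprint_features <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  bits <- ChemmineOB::fingerprint_OB(mol, "FP2")
  feats <- which(as.numeric(bits) != 0)
  if (length(feats) == 0L) stop("no fingerprint features for ", sQuote(smiles))
  sort(feats)
}

#' Dice similarity between two feature sets
#'
#' `2 |A n B| / (|A| + |B|)`, symmetric, in `[0, 1]`. Undefined when both sets
#' are empty.
#'
#' @param a,b feature sets (vectors; duplicates are ignored).
#' @return similarity in `[0, 1]`.
#' @export
dice_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("Dice similarity is undefined for two empty feature sets")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Assign structural alerts by Dice similarity
#'
#' A target is assigned every alert whose profile feature set reaches at least
#' `threshold` Dice similarity (boundary inclusive). Results are sorted by
#' descending similarity with ties broken by alert name, so output is stable
#' under permutation of the profile map. Alert assignments are preliminary
#' indicators for screening, not definitive toxicological assessments.
#'
#' @param target feature set of the target chemical.
#' @param alert_profiles named list of alert feature sets.
#' @param threshold similarity cut-off, default 0.5.
#' @return data frame `alert`, `similarity` (possibly zero rows), with
#'   attribute `note = "preliminary indicators"`.
#' @export
assign_alerts <- function(target, alert_profiles, threshold = 0.5) {
  if (length(alert_profiles) == 0L) stop("alert_profiles must be non-empty")
  if (is.null(names(alert_profiles)) || any(!nzchar(names(alert_profiles)))) {
    stop("alert_profiles must be named")
  }
  sims <- vapply(alert_profiles, function(p) dice_similarity(target, p),
                 numeric(1))
  out <- data.frame(alert = names(sims), similarity = unname(sims),
                    stringsAsFactors = FALSE)
  out <- out[out$similarity >= threshold, , drop = FALSE]
  out <- out[order(-out$similarity, out$alert), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "note") <- "preliminary indicators"
  out
}

#' Validate a CAS registry number
#'
#' Format `digits-digits-checkdigit` plus the standard check-digit rule
#' (digits weighted 1..n from the right, sum mod 10). Validation failures are
#' reported to callers as warnings, not fatal errors, since legacy numbers
#' occur in curated sources.
#'
#' @param cas character vector of CAS numbers.
#' @return logical vector.
#' @export
cas_checksum_ok <- function(cas) {
  one <- function(x) {
    if (is.na(x)) return(NA)
    if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    check <- digits[n]
    body <- rev(digits[-n])
    sum(body * seq_along(body)) %% 10 == check
  }
  vapply(cas, one, logical(1), USE.NAMES = FALSE)
}

# ---- fuzzy name search ------------------------------------------------------

#' Build a name index over compound records
#'
#' Keys are normalized with [normalize_name()] (lowercase, punctuation
#' variants like "No." / "No" / "No.15" collapsed, whitespace squashed), so
#' the spelling variants seen across opinions resolve to one entry.
#'
#' @param compounds data frame with `compound_id` and `ingredient_name`
#'   (optionally `inci_name`).
#' @return an object of class `name_index`.
#' @export
name_index <- function(compounds) {
  names_ <- compounds$ingredient_name
  ids <- compounds$compound_id
  if (!is.null(compounds$inci_name)) {
    extra <- !is.na(compounds$inci_name) & nzchar(compounds$inci_name)
    names_ <- c(names_, compounds$inci_name[extra])
    ids <- c(ids, compounds$compound_id[extra])
  }
  structure(
    list(entries = data.frame(key = normalize_name(names_), name = names_,
                              compound_id = ids, stringsAsFactors = FALSE)),
    class = "name_index"
  )
}

# normalized edit-distance similarity in [0,1]
string_similarity <- function(a, b) {
  d <- as.numeric(utils::adist(a, b))
  m <- pmax(nchar(a), nchar(b))
  ifelse(m == 0, 1, 1 - d / m)
}

#' Search compound names
#'
#' Proportional mode ranks all entries by normalized edit-distance similarity
#' and retains the best `threshold` fraction, always including substring
#' matches (searching "yellow" returns every ingredient with "yellow" in its
#' name). Hard mode retains entries with similarity at or above `threshold`
#' (e.g. 0.95 for "95% similarity").
#'
#' @param index a [name_index()].
#' @param query search string (case/punctuation-insensitive).
#' @param mode `"proportional"` (default) or `"hard"`.
#' @param threshold top fraction to keep (proportional) or minimum similarity
#'   (hard).
#' @return data frame `compound_id`, `name`, `similarity`, `substring_match`,
#'   ranked by descending similarity (substring matches first), ties broken by
#'   name.
#' @export
search_names <- function(index, query, mode = c("proportional", "hard"),
                         threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "hard") 0.95 else 0.25
  stopifnot(inherits(index, "name_index"))
  qn <- normalize_name(query)
  e <- index$entries
  e$similarity <- string_similarity(qn, e$key)
  e$substring_match <- grepl(qn, e$key, fixed = TRUE)
  if (mode == "hard") {
    keep <- e$similarity >= threshold
  } else {
    n_keep <- max(1L, ceiling(threshold * nrow(e)))
    ranked <- order(-e$similarity, e$name)
    keep <- logical(nrow(e))
    keep[ranked[seq_len(n_keep)]] <- TRUE
    keep <- keep | e$substring_match
  }
  out <- e[keep, c("compound_id", "name", "similarity", "substring_match")]
  out <- out[order(-out$substring_match, -out$similarity, out$name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
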