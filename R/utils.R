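# Small shared helpers: path escaping, label/name normalization, slugs.

#' Split a slash-delimited concept path into segments
#'
#' Property names may themselves contain a slash (e.g. `"dose-volume ml/kg bw"`);
#' in the canonical serialized form such slashes are escaped as `\/`.
#'
#' @param path character scalar, e.g. `"Test method/Test condition/dose levels"`.
#' @return character vector of unescaped segments.
#' @export
split_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  segs <- strsplit(path, "(?<!\\\\)/", perl = TRUE)[[1]]
  gsub("\\\\/", "/", segs)
}

#' Join path segments, escaping embedded slashes
#'
#' @param segments character vector of raw segment names.
#' @return character scalar in canonical escaped form.
#' @export
join_path <- function(segments) {
  paste(gsub("/", "\\\\/", segments), collapse = "/")
}

# lowercase, collapse runs of whitespace, trim
squash_ws <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalize a label for matching
#'
#' Case-insensitive, whitespace-collapsed comparison form used for `sameAs`
#' label matching and name lookups.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  tolower(squash_ws(x))
}

#' Normalize an ingredient name for the name index
#'
#' Lowercases, strips periods and commas (so "No." and "No" agree), inserts a
#' space at letter-digit boundaries (so "No.15" and "No. 15" agree) and
#' collapses whitespace. Idempotent.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[.,']", " ", x)
  x <- gsub("([a-z])([0-9])", "\\1 \\2", x)
  x <- gsub("([0-9])([a-z])", "\\1 \\2", x)
  squash_ws(x)
}

# URL-safe slug for IRI minting; deterministic.
slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "-", x)
  gsub("^-+|-+$", "", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE when a field value counts as "present" for evidence purposes
is_present <- function(x) {
  !is.null(x) && !all(is.na(x)) && any(nzchar(trimws(as.character(x))))
}
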