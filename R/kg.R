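# Lightweight RDF quad store: triples in named graphs, kept as a data frame
# with deterministic canonical ordering so serialized output is diffable.
# Includes Turtle/TriG/N-Quads writers and a restrained Turtle reader
# sufficient for ontology fixtures (prefix declarations, `a`, `;`/`,` lists,
# plain and language-tagged literals, comments).

DEFAULT_NAMESPACES <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  tx   = "http://example.org/toxin/",
  txo  = "http://example.org/txpo/"
)

KG_GRAPHS <- c("internal", "external_links", "inferred", "ontology")

empty_quads <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), literal = logical(0),
             graph = character(0), stringsAsFactors = FALSE)
}

#' Create an empty knowledge graph
#'
#' Quads live in named graphs that separate data by origin: `internal`
#' (mapped from the curated dataset), `ontology` (imported fixture/ontology
#' triples), `external_links` (label-matched `sameAs` links) and `inferred`
#' (reasoned links). The separation keeps information origins traceable.
#'
#' @param namespaces named character vector prefix -> IRI base.
#' @return an object of class `kgraph`.
#' @export
kg_new <- function(namespaces = DEFAULT_NAMESPACES) {
  structure(list(quads = empty_quads(), namespaces = namespaces),
            class = "kgraph")
}

#' Expand a compact (prefix:local) IRI
#'
#' @param x character vector of compact or absolute IRIs.
#' @param namespaces prefix map.
#' @return absolute IRIs.
#' @export
kg_expand <- function(x, namespaces = DEFAULT_NAMESPACES) {
  one <- function(v) {
    if (grepl("^https?://", v)) return(v)
    m <- regmatches(v, regexec("^([A-Za-z][A-Za-z0-9_-]*):(.*)$", v))[[1]]
    if (length(m) == 3 && m[2] %in% names(namespaces)) {
      return(paste0(namespaces[[m[2]]], m[3]))
    }
    v
  }
  vapply(x, one, character(1), USE.NAMES = FALSE)
}

#' Add quads to a knowledge graph
#'
#' Subjects/predicates (and IRI objects) may be compact; they are expanded
#' against the graph's namespaces. Duplicate quads collapse (set semantics).
#'
#' @param kg a `kgraph`.
#' @param subject,predicate,object vectors (recycled to a common length).
#' @param graph target named graph.
#' @param literal logical vector: is `object` a literal?
#' @return the updated `kgraph`.
#' @export
kg_add <- function(kg, subject, predicate, object, graph = "internal",
                   literal = FALSE) {
  stopifnot(inherits(kg, "kgraph"))
  graph <- match.arg(graph, KG_GRAPHS)
  n <- max(length(subject), length(predicate), length(object), length(literal))
  add <- data.frame(
    subject = kg_expand(rep_len(subject, n), kg$namespaces),
    predicate = kg_expand(rep_len(predicate, n), kg$namespaces),
    object = rep_len(as.character(object), n),
    literal = rep_len(literal, n),
    graph = rep_len(graph, n),
    stringsAsFactors = FALSE
  )
  add$object[!add$literal] <- kg_expand(add$object[!add$literal], kg$namespaces)
  kg$quads <- unique(rbind(kg$quads, add))
  kg
}

#' Quads of a knowledge graph
#'
#' @param kg a `kgraph`.
#' @param graph optional named-graph filter.
#' @return data frame of quads in canonical order (graph, subject, predicate,
#'   object).
#' @export
kg_quads <- function(kg, graph = NULL) {
  q <- kg$quads
  if (!is.null(graph)) q <- q[q$graph %in% graph, , drop = FALSE]
  q <- q[order(q$graph, q$subject, q$predicate, q$object, q$literal), ,
         drop = FALSE]
  rownames(q) <- NULL
  q
}

#' @export
print.kgraph <- function(x, ...) {
  cat("<kgraph>", nrow(x$quads), "quads\n")
  tab <- table(x$quads$graph)
  for (g in names(tab)) cat("  ", g, ":", tab[[g]], "\n")
  invisible(x)
}

#' Number of quads
#' @param kg a `kgraph`.
#' @param graph optional named-graph filter.
#' @return integer count.
#' @export
kg_size <- function(kg, graph = NULL) nrow(kg_quads(kg, graph))

# objects of (subject, predicate) pairs
kg_objects <- function(kg, subject = NULL, predicate = NULL, graph = NULL) {
  q <- kg_quads(kg, graph)
  if (!is.null(subject)) q <- q[q$subject %in% subject, , drop = FALSE]
  if (!is.null(predicate)) q <- q[q$predicate %in% predicate, , drop = FALSE]
  q$object
}

# rdfs:label lookup; returns NA when absent
kg_label <- function(kg, iri, graph = NULL) {
  labs <- kg_objects(kg, subject = iri,
                     predicate = kg_expand("rdfs:label"), graph = graph)
  if (length(labs)) labs[[1]] else NA_character_
}

# ---- serialization ----------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

term_nt <- function(object, literal) {
  ifelse(literal, paste0("\"", escape_literal(object), "\""),
         paste0("<", object, ">"))
}

graph_iri <- function(g, namespaces) {
  paste0(namespaces[["tx"]], "graph/", g)
}

graph_from_iri <- function(iri, namespaces) {
  sub(paste0("^", namespaces[["tx"]], "graph/"), "", iri)
}

#' Write a knowledge graph as N-Quads
#'
#' Canonically ordered (graph, subject, predicate, object) for diffable
#' output; round-trips losslessly through [read_nquads()].
#'
#' @param kg a `kgraph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nquads <- function(kg, path) {
  q <- kg_quads(kg)
  lines <- paste0("<", q$subject, "> <", q$predicate, "> ",
                  term_nt(q$object, q$literal), " <",
                  graph_iri(q$graph, kg$namespaces), "> .")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an N-Quads file
#'
#' @param path N-Quads file written by [write_nquads()].
#' @param namespaces prefix map for the resulting graph.
#' @return a `kgraph`.
#' @export
read_nquads <- function(path, namespaces = DEFAULT_NAMESPACES) {
  kg <- kg_new(namespaces)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  pat <- "^<([^>]*)> <([^>]*)> (<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\") <([^>]*)> \\.$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed N-Quads line: ", lines[which(bad)[1]])
  rows <- do.call(rbind, lapply(m, function(x) {
    obj <- x[4]
    lit <- startsWith(obj, "\"")
    data.frame(subject = x[2], predicate = x[3],
               object = if (lit) unescape_literal(substr(obj, 2, nchar(obj) - 1))
                        else substr(obj, 2, nchar(obj) - 1),
               literal = lit,
               graph = graph_from_iri(x[5], namespaces),
               stringsAsFactors = FALSE)
  }))
  kg$quads <- unique(rows)
  kg
}

#' Write a knowledge graph as TriG
#'
#' One `GRAPH <iri> { ... }` block per named graph, canonically ordered.
#'
#' @param kg a `kgraph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trig <- function(kg, path) {
  q <- kg_quads(kg)
  out <- character(0)
  for (g in unique(q$graph)) {
    qi <- q[q$graph == g, , drop = FALSE]
    out <- c(out, paste0("GRAPH <", graph_iri(g, kg$namespaces), "> {"),
             paste0("  <", qi$subject, "> <", qi$predicate, "> ",
                    term_nt(qi$object, qi$literal), " ."),
             "}")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a TriG file written by [write_trig()]
#'
#' @param path TriG file.
#' @param namespaces prefix map for the resulting graph.
#' @return a `kgraph`.
#' @export
read_trig <- function(path, namespaces = DEFAULT_NAMESPACES) {
  kg <- kg_new(namespaces)
  lines <- readLines(path, encoding = "UTF-8")
  graph <- NA_character_
  rows <- list()
  tri_pat <- "^\\s*<([^>]*)> <([^>]*)> (<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\") \\.$"
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (grepl("^GRAPH <", t)) {
      graph <- graph_from_iri(sub("^GRAPH <([^>]*)> \\{$", "\\1", t), namespaces)
    } else if (identical(t, "}")) {
      graph <- NA_character_
    } else {
      m <- regmatches(ln, regexec(tri_pat, ln))[[1]]
      if (length(m) != 4L) stop("malformed TriG line: ", ln)
      obj <- m[4]
      lit <- startsWith(obj, "\"")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = m[2], predicate = m[3],
        object = if (lit) unescape_literal(substr(obj, 2, nchar(obj) - 1))
                 else substr(obj, 2, nchar(obj) - 1),
        literal = lit, graph = graph, stringsAsFactors = FALSE)
    }
  }
  kg$quads <- unique(do.call(rbind, c(rows, list(empty_quads()))))
  kg
}

#' Write one named graph as Turtle
#'
#' @param kg a `kgraph`.
#' @param path output file.
#' @param graph which named graph to export (default: all quads, merged).
#' @return `path`, invisibly.
#' @export
write_turtle <- function(kg, path, graph = NULL) {
  q <- kg_quads(kg, graph)
  lines <- paste0("<", q$subject, "> <", q$predicate, "> ",
                  term_nt(q$object, q$literal), " .")
  writeLines(unique(lines), path, useBytes = TRUE)
  invisible(path)
}

# ---- restrained Turtle reader ----------------------------------------------

tokenize_turtle <- function(text) {
  tokens <- character(0)
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "#") {  # comment to end of line
      j <- regexpr("\n", substr(text, i, n), fixed = TRUE)
      i <- if (j == -1L) n + 1L else i + j
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j == -1L) stop("unterminated IRI in Turtle input")
      tokens <- c(tokens, substr(text, i, i + j - 1L))
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\"") break
        j <- j + 1L
      }
      if (j > n) stop("unterminated literal in Turtle input")
      # optional language tag
      lit <- substr(text, i, j)
      i <- j + 1L
      if (substr(text, i, i) == "@") {
        k <- regexpr("[^A-Za-z0-9-]", substr(text, i + 1L, n))
        skip <- if (k == -1L) n - i + 1L else k
        i <- i + skip
      }
      tokens <- c(tokens, lit)
      next
    }
    if (ch %in% c(".", ";", ",")) {
      tokens <- c(tokens, ch)
      i <- i + 1L
      next
    }
    j <- regexpr("[][[:space:];,.<\"]", substr(text, i, n))
    end <- if (j == -1L) n else i + j - 2L
    tok <- substr(text, i, end)
    # a prefixed name may legitimately end before the statement dot
    tokens <- c(tokens, tok)
    i <- end + 1L
  }
  tokens
}

#' Read a Turtle file into a named graph
#'
#' Restrained Turtle subset: `@prefix` declarations, absolute and prefixed
#' IRIs, the `a` keyword, predicate (`;`) and object (`,`) lists, plain and
#' language-tagged string literals, `#` comments. Sufficient for ontology
#' fixtures; not a full Turtle implementation.
#'
#' @param path Turtle file.
#' @param graph target named graph (default `"ontology"`).
#' @param namespaces initial prefix map (extended by `@prefix` lines).
#' @return a `kgraph` holding the file's triples in `graph`.
#' @export
read_turtle <- function(path, graph = "ontology",
                        namespaces = DEFAULT_NAMESPACES) {
  text <- paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
  tokens <- tokenize_turtle(text)
  ns <- namespaces
  rows <- list()
  i <- 1L
  term <- function(tok) {
    if (startsWith(tok, "<")) {
      list(value = substr(tok, 2, nchar(tok) - 1L), literal = FALSE)
    } else if (startsWith(tok, "\"")) {
      list(value = unescape_literal(substr(tok, 2, nchar(tok) - 1L)),
           literal = TRUE)
    } else if (identical(tok, "a")) {
      list(value = paste0(ns[["rdf"]], "type"), literal = FALSE)
    } else {
      list(value = kg_expand(tok, ns), literal = FALSE)
    }
  }
  while (i <= length(tokens)) {
    if (identical(tokens[i], "@prefix")) {
      pfx <- sub(":$", "", tokens[i + 1L])
      iri <- tokens[i + 2L]
      ns[pfx] <- substr(iri, 2, nchar(iri) - 1L)
      stopifnot(identical(tokens[i + 3L], "."))
      i <- i + 4L
      next
    }
    subj <- term(tokens[i])$value
    i <- i + 1L
    repeat {
      pred <- term(tokens[i])$value
      i <- i + 1L
      repeat {
        obj <- term(tokens[i])
        i <- i + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, predicate = pred, object = obj$value,
          literal = obj$literal, graph = graph, stringsAsFactors = FALSE)
        if (identical(tokens[i], ",")) { i <- i + 1L; next }
        break
      }
      if (identical(tokens[i], ";")) {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (identical(tokens[i], ".")) break
        next
      }
      break
    }
    stopifnot(identical(tokens[i], "."))
    i <- i + 1L
  }
  kg <- kg_new(ns)
  kg$quads <- unique(do.call(rbind, c(rows, list(empty_quads()))))
  kg
}
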