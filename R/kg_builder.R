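# Builds the knowledge graph from a curated dataset via declarative,
# R2RML-inspired mapping rules (no SQL layer), links it to an ontology by
# normalized-label matching ("sameAs"), infers "is affected by" edges by
# counting adverse effects shared between an opinion's observations and a
# disease/toxic-process effect profile, and answers the three competency
# questions.

RDF_TYPE <- "rdf:type"
RDFS_LABEL <- "rdfs:label"
OWL_SAMEAS <- "owl:sameAs"
TXO_HAS_CONTEXT <- "txo:has_context"
TXO_HAS_PART <- "txo:has_part"
TXO_IS_A <- "txo:is_a"
TXO_PATHWAY <- "txo:pathway_association"
TXO_PARTICIPANT <- "txo:has_participant"

#' Effect-token alignment table
#'
#' Bridges (canonical parameter, direction) findings to the ontology's
#' adverse-effect labels, e.g. `(ALP, increase)` to
#' `"increased blood ALP concentration"`.
#'
#' @param path CSV with columns `parameter`, `direction`, `token`; defaults
#'   to the shipped table.
#' @return data frame.
#' @export
effect_token_alignment <- function(path = NULL) {
  if (is.null(path)) path <- tkg_file("extdata", "effect_token_alignment.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Canonical effect token for a finding
#'
#' @param parameter canonical parameter token(s).
#' @param direction direction(s).
#' @param alignment alignment table (see [effect_token_alignment()]).
#' @return character vector of effect tokens; unaligned findings fall back to
#'   `"<direction> <parameter>"`.
#' @export
effect_token <- function(parameter, direction,
                         alignment = effect_token_alignment()) {
  key <- paste(parameter, direction, sep = "\r")
  akey <- paste(alignment$parameter, alignment$direction, sep = "\r")
  hit <- alignment$token[match(key, akey)]
  ifelse(is.na(hit), paste(direction, parameter), hit)
}

#' Deterministic IRI for a compound
#'
#' Keyed by CAS number when present, else by the slugged ingredient name.
#'
#' @param compounds compound data frame rows.
#' @return character vector of absolute-compactable IRIs (`tx:` prefix).
#' @export
compound_iri <- function(compounds) {
  cas <- compounds$cas_number
  has_cas <- !is.na(cas) & nzchar(cas)
  ifelse(has_cas, paste0("tx:compound/cas-", cas),
         paste0("tx:compound/", slugify(compounds$ingredient_name)))
}

#' Default R2RML-inspired mapping rules
#'
#' Each rule names a source table, a subject template, a predicate, and an
#' object (column reference or constant). Templates reference prepared
#' columns with `{column}`; applying a rule to n rows yields at most n quads
#' (rows with empty object cells are skipped).
#'
#' @return list of mapping rules.
#' @export
default_mapping_rules <- function() {
  rule <- function(source, subject, predicate, object, literal = TRUE,
                   constant = FALSE) {
    list(source = source, subject = subject, predicate = predicate,
         object = object, literal = literal, constant = constant)
  }
  list(
    rule("compounds", "{iri}", RDF_TYPE, "tx:Compound", FALSE, constant = TRUE),
    rule("compounds", "{iri}", RDFS_LABEL, "ingredient_name"),
    rule("compounds", "{iri}", "tx:casNumber", "cas_number"),
    rule("compounds", "{iri}", "tx:useCategory", "use_category"),
    rule("compounds", "{iri}", "tx:canonicalSmiles", "canonical_smiles"),
    rule("opinions", "{iri}", RDF_TYPE, "tx:Opinion", FALSE, constant = TRUE),
    rule("opinions", "{iri}", RDFS_LABEL, "opinion_id"),
    rule("opinions", "{iri}", "tx:aboutCompound", "compound_iri", FALSE),
    rule("opinions", "{iri}", "tx:year", "year"),
    rule("studies", "{iri}", RDF_TYPE, "tx:Study", FALSE, constant = TRUE),
    rule("studies", "{iri}", RDFS_LABEL, "study_id"),
    rule("studies", "{iri}", "tx:guideline", "guideline_id"),
    rule("studies", "{iri}", "tx:ofOpinion", "opinion_iri", FALSE),
    rule("studies", "{iri}", "tx:aboutCompound", "compound_iri", FALSE),
    rule("observations", "{iri}", RDF_TYPE, "tx:Observation", FALSE,
         constant = TRUE),
    rule("observations", "{iri}", RDFS_LABEL, "token"),
    rule("observations", "{iri}", "tx:parameter", "parameter"),
    rule("observations", "{iri}", "tx:direction", "direction"),
    rule("observations", "{opinion_iri}", "tx:hasObservation", "iri", FALSE)
  )
}

apply_rule <- function(kg, rule, tables) {
  tab <- tables[[rule$source]]
  if (is.null(tab) || nrow(tab) == 0L) return(kg)
  fill_template <- function(tpl) {
    refs <- regmatches(tpl, gregexpr("\\{[^}]+\\}", tpl))[[1]]
    out <- rep(tpl, nrow(tab))
    for (r in refs) {
      col <- substr(r, 2, nchar(r) - 1L)
      if (is.null(tab[[col]])) {
        stop("mapping error in rule (", rule$source, " -> ", rule$predicate,
             "): template references missing column ", sQuote(col))
      }
      out <- mapply(gsub, pattern = r, replacement = as.character(tab[[col]]),
                    x = out, MoreArgs = list(fixed = TRUE), USE.NAMES = FALSE)
    }
    out
  }
  subjects <- fill_template(rule$subject)
  if (rule$constant) {
    objects <- rep(rule$object, nrow(tab))
  } else {
    if (is.null(tab[[rule$object]])) {
      stop("mapping error in rule (", rule$source, " -> ", rule$predicate,
           "): object references missing column ", sQuote(rule$object))
    }
    objects <- as.character(tab[[rule$object]])
  }
  keep <- !is.na(objects) & nzchar(objects)
  if (!any(keep)) return(kg)
  kg_add(kg, subjects[keep], rule$predicate, objects[keep],
         graph = "internal", literal = rule$literal)
}

# liver-finding study fields mapped to effect observations (histopathology
# and hepatocellular-effect blocks)
study_observation_rows <- function(studies, opinion_iri_of, alignment) {
  rows <- list()
  for (rec in studies) {
    op_iri <- opinion_iri_of(rec)
    for (p in names(rec$fields)) {
      segs <- split_path(p)
      last <- segs[[length(segs)]]
      val <- as.character(rec$fields[[p]])
      if (identical(segs[1], "Pathology") && toupper(val) == "YES") {
        canon <- normalize_parameter(last)
        if (is.na(canon)) next
        token <- effect_token(canon, "increase", alignment)
        rows[[length(rows) + 1L]] <- data.frame(
          iri = paste0("tx:observation/", slugify(rec$study_id), "/",
                       slugify(canon)),
          opinion_iri = op_iri, parameter = canon, direction = "increase",
          token = token, stringsAsFactors = FALSE)
      } else if (identical(segs[1], "Clinical biochemistry")) {
        dirn <- normalize_direction(val)
        canon <- normalize_parameter(last)
        if (is.na(dirn) || is.na(canon)) next
        token <- effect_token(canon, dirn, alignment)
        rows[[length(rows) + 1L]] <- data.frame(
          iri = paste0("tx:observation/", slugify(rec$study_id), "/",
                       slugify(canon)),
          opinion_iri = op_iri, parameter = canon, direction = dirn,
          token = token, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(data.frame(iri = character(0),
                                         opinion_iri = character(0),
                                         parameter = character(0),
                                         direction = character(0),
                                         token = character(0)))))
}

#' Build the internal knowledge graph from a dataset
#'
#' Applies the mapping rules to the dataset's tables. Every produced quad
#' lives in the `internal` named graph. IRI minting is deterministic: the
#' same dataset always yields the same quad set. Observations (from the
#' effects table and from liver-relevant study fields) attach to the
#' compound's most recent opinion; compounds without an opinion get a
#' deterministic implicit one.
#'
#' @param dataset a `toxin_dataset`.
#' @param rules mapping rules, see [default_mapping_rules()].
#' @param alignment effect-token alignment table.
#' @return a `kgraph` with the `internal` graph populated.
#' @export
build_kg <- function(dataset, rules = default_mapping_rules(),
                     alignment = effect_token_alignment()) {
  stopifnot(inherits(dataset, "toxin_dataset"))
  kg <- kg_new()

  compounds <- dataset$compounds
  compounds$iri <- if (nrow(compounds)) compound_iri(compounds) else character(0)
  if (is.null(compounds$canonical_smiles)) {
    compounds$canonical_smiles <- rep("", nrow(compounds))
  }
  iri_of_compound <- setNames(compounds$iri, compounds$compound_id)

  opinions <- dataset$opinions
  # implicit opinion for compounds carrying findings but no opinion row
  need <- setdiff(unique(c(dataset$effects$compound_id,
                           vapply(dataset$studies, `[[`, character(1),
                                  "compound_id"))),
                  opinions$compound_id)
  need <- intersect(need, compounds$compound_id)
  if (length(need)) {
    opinions <- rbind(opinions[, c("opinion_id", "year", "compound_id",
                                   "is_placeholder")],
                      data.frame(opinion_id = paste0("implicit-", need),
                                 year = NA_integer_, compound_id = need,
                                 is_placeholder = TRUE))
  }
  if (nrow(opinions)) {
    opinions$iri <- paste0("tx:opinion/", slugify(opinions$opinion_id))
    opinions$compound_iri <- unname(iri_of_compound[opinions$compound_id])
  }
  # most recent opinion per compound carries the conclusions
  latest_opinion_iri <- character(0)
  if (nrow(opinions)) {
    ord <- order(opinions$compound_id, -ifelse(is.na(opinions$year), 0,
                                               opinions$year),
                 opinions$opinion_id)
    oo <- opinions[ord, ]
    first <- !duplicated(oo$compound_id)
    latest_opinion_iri <- setNames(oo$iri[first], oo$compound_id[first])
  }

  studies_tab <- NULL
  if (length(dataset$studies)) {
    studies_tab <- do.call(rbind, lapply(dataset$studies, function(rec) {
      data.frame(study_id = rec$study_id,
                 iri = paste0("tx:study/", slugify(rec$study_id)),
                 guideline_id = rec$guideline_id,
                 compound_iri = unname(iri_of_compound[rec$compound_id]) %||%
                   NA_character_,
                 opinion_iri = if (!is.na(rec$opinion_id %||% NA) &&
                                   nzchar(rec$opinion_id)) {
                   paste0("tx:opinion/", slugify(rec$opinion_id))
                 } else {
                   unname(latest_opinion_iri[rec$compound_id]) %||% NA_character_
                 },
                 stringsAsFactors = FALSE)
    }))
  }

  effects <- dataset$effects
  obs <- NULL
  if (nrow(effects)) {
    obs <- data.frame(
      iri = paste0("tx:observation/", effects$compound_id, "/",
                   slugify(effects$parameter), "/", effects$direction),
      opinion_iri = unname(latest_opinion_iri[effects$compound_id]),
      parameter = effects$parameter, direction = effects$direction,
      token = effect_token(effects$parameter, effects$direction, alignment),
      stringsAsFactors = FALSE)
  }
  opinion_iri_of <- function(rec) {
    if (!is.na(rec$opinion_id %||% NA) && nzchar(rec$opinion_id)) {
      paste0("tx:opinion/", slugify(rec$opinion_id))
    } else {
      unname(latest_opinion_iri[rec$compound_id])
    }
  }
  obs_study <- study_observation_rows(dataset$studies, opinion_iri_of,
                                      alignment)
  observations <- unique(rbind(obs, obs_study))
  if (!is.null(observations) && nrow(observations)) {
    observations <- observations[!is.na(observations$opinion_iri), ,
                                 drop = FALSE]
  }

  tables <- list(compounds = compounds, opinions = opinions,
                 studies = studies_tab, observations = observations)
  for (rule in rules) kg <- apply_rule(kg, rule, tables)
  kg
}

#' Link internal entities to ontology entities by label ("sameAs")
#'
#' Imports the ontology's triples into the `ontology` named graph (kept
#' separate from internal data) and emits one `owl:sameAs` quad into
#' `external_links` for every internal/ontology pair whose normalized labels
#' match exactly (case-insensitive, whitespace-collapsed). One internal label
#' matching several ontology entities emits all links plus a warning —
#' linking errors are noncritical and traceable.
#'
#' @param kg a `kgraph` built by [build_kg()].
#' @param ontology a `kgraph` holding ontology triples (see [read_turtle()]).
#' @return the updated `kgraph`.
#' @export
link_same_as <- function(kg, ontology) {
  onto_quads <- ontology$quads
  onto_quads$graph <- "ontology"
  kg$quads <- unique(rbind(kg$quads, onto_quads))

  label_pred <- kg_expand(RDFS_LABEL)
  internal <- kg_quads(kg, "internal")
  ilab <- internal[internal$predicate == label_pred, , drop = FALSE]
  onto <- kg_quads(kg, "ontology")
  olab <- onto[onto$predicate == label_pred, , drop = FALSE]
  if (nrow(ilab) == 0L || nrow(olab) == 0L) return(kg)
  ikey <- normalize_label(ilab$object)
  okey <- normalize_label(olab$object)
  for (i in seq_len(nrow(ilab))) {
    hits <- unique(olab$subject[okey == ikey[i]])
    if (length(hits) == 0L) next
    if (length(hits) > 1L) {
      warning("ambiguous sameAs: internal label ", sQuote(ilab$object[i]),
              " matches ", length(hits), " ontology entities", call. = FALSE)
    }
    kg <- kg_add(kg, rep(ilab$subject[i], length(hits)), OWL_SAMEAS, hits,
                 graph = "external_links", literal = FALSE)
  }
  kg
}

# is_a ancestor closure for one entity (IRIs), cycle-safe
isa_ancestors <- function(entity, isa_edges) {
  out <- character(0)
  frontier <- entity
  while (length(frontier)) {
    parents <- unique(isa_edges$object[isa_edges$subject %in% frontier])
    parents <- setdiff(parents, c(out, entity))
    out <- c(out, parents)
    frontier <- parents
  }
  out
}

#' Effect profiles of the ontology's diseases and toxic processes
#'
#' A profile entity is anything that is the context of at least one adverse
#' effect (`has_context`). Its effect set is the normalized labels of its
#' contextual effects, closed under `is_a` inheritance: a subtype inherits
#' its ancestors' effects (NAFLD, a lipidosis, carries the lipidosis
#' effects).
#'
#' @param kg a `kgraph` containing an `ontology` graph (or an ontology
#'   `kgraph` itself).
#' @return named list of profiles: each has `entity` (IRI), `label`, and
#'   `effects` (character vector of normalized effect labels).
#' @export
effect_profiles <- function(kg) {
  graphs <- intersect(c("ontology"), unique(kg$quads$graph))
  q <- if (length(graphs)) kg_quads(kg, graphs) else kg_quads(kg)
  ctx <- q[q$predicate == kg_expand(TXO_HAS_CONTEXT), , drop = FALSE]
  isa <- q[q$predicate == kg_expand(TXO_IS_A), , drop = FALSE]
  lab <- q[q$predicate == kg_expand(RDFS_LABEL), , drop = FALSE]
  label_of <- setNames(lab$object, lab$subject)
  entities <- sort(unique(c(ctx$object, isa$subject)))
  own <- function(e) {
    effs <- ctx$subject[ctx$object == e]
    normalize_label(unname(label_of[effs]))
  }
  profiles <- lapply(entities, function(e) {
    effs <- unique(c(own(e), unlist(lapply(isa_ancestors(e, isa), own))))
    list(entity = e, label = unname(label_of[e]) %||% NA_character_,
         effects = sort(effs[!is.na(effs)]))
  })
  names(profiles) <- entities
  profiles
}

# observation tokens per opinion (normalized labels of its observations)
opinion_tokens <- function(kg) {
  internal <- kg_quads(kg, "internal")
  has_obs <- internal[internal$predicate == kg_expand("tx:hasObservation"), ,
                      drop = FALSE]
  lab <- internal[internal$predicate == kg_expand(RDFS_LABEL), , drop = FALSE]
  label_of <- setNames(lab$object, lab$subject)
  split_tokens <- split(normalize_label(unname(label_of[has_obs$object])),
                        has_obs$subject)
  lapply(split_tokens, function(t) sort(unique(t[!is.na(t)])))
}

#' Infer "is affected by" links
#'
#' For each (opinion, profile) pair, counts the adverse-effect tokens shared
#' between the opinion's observations and the profile's effect set (closed
#' under `is_a` inheritance). A link is emitted into the `inferred` named
#' graph iff the shared count reaches `min_shared`; the count is annotated as
#' likelihood evidence. The default `min_shared = 2` treats a single shared
#' generic effect as weak evidence.
#'
#' @param kg a `kgraph` after [build_kg()] and [link_same_as()].
#' @param profiles effect profiles; defaults to [effect_profiles()] of `kg`.
#' @param min_shared minimum shared-effect count (>= 1).
#' @return the updated `kgraph`; retrieve the link table with
#'   [affected_by_links()].
#' @export
infer_affected_by <- function(kg, profiles = NULL, min_shared = 2) {
  stopifnot(min_shared >= 1)
  if (is.null(profiles)) profiles <- effect_profiles(kg)
  tokens <- opinion_tokens(kg)
  for (op in names(tokens)) {
    for (pr in profiles) {
      shared <- length(intersect(tokens[[op]], pr$effects))
      if (shared >= min_shared) {
        link <- paste0("tx:affected/", slugify(sub(".*/", "", op)), "/",
                       slugify(sub(".*/", "", pr$entity)))
        kg <- kg_add(kg, op, "tx:isAffectedBy", pr$entity,
                     graph = "inferred", literal = FALSE)
        kg <- kg_add(kg, link, "tx:linkSubject", op, "inferred", FALSE)
        kg <- kg_add(kg, link, "tx:linkEntity", pr$entity, "inferred", FALSE)
        kg <- kg_add(kg, link, "tx:sharedEffectCount", as.character(shared),
                     "inferred", TRUE)
      }
    }
  }
  kg
}

#' Inferred "is affected by" link table
#'
#' @param kg a `kgraph` after [infer_affected_by()].
#' @return data frame `subject` (opinion IRI), `entity` (disease/toxic
#'   process IRI), `shared_count`.
#' @export
affected_by_links <- function(kg) {
  inf <- kg_quads(kg, "inferred")
  subj <- inf[inf$predicate == kg_expand("tx:linkSubject"), , drop = FALSE]
  ent <- inf[inf$predicate == kg_expand("tx:linkEntity"), , drop = FALSE]
  cnt <- inf[inf$predicate == kg_expand("tx:sharedEffectCount"), , drop = FALSE]
  out <- data.frame(
    link = subj$subject,
    subject = subj$object,
    entity = ent$object[match(subj$subject, ent$subject)],
    shared_count = as.integer(cnt$object[match(subj$subject, cnt$subject)]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$shared_count, out$subject, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("subject", "entity", "shared_count")]
}

# nodes reachable from `start` over the given predicates, including edges
# inherited from is_a ancestors
reachable <- function(q, start, predicates, isa_edges) {
  preds <- kg_expand(predicates)
  seen <- character(0)
  frontier <- start
  while (length(frontier)) {
    from <- unique(c(frontier, unlist(lapply(frontier, isa_ancestors,
                                             isa_edges = isa_edges))))
    nxt <- unique(q$object[q$subject %in% from & q$predicate %in% preds &
                             !q$literal])
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

resolve_entity <- function(kg, x) {
  if (grepl("^https?://", x)) return(x)
  expanded <- kg_expand(x, kg$namespaces)
  if (grepl("^https?://", expanded) &&
      expanded %in% c(kg$quads$subject, kg$quads$object)) {
    return(expanded)
  }
  lab <- kg$quads[kg$quads$predicate == kg_expand(RDFS_LABEL) &
                    normalize_label(kg$quads$object) == normalize_label(x), ,
                  drop = FALSE]
  if (nrow(lab)) lab$subject[[1]] else expanded
}

#' Answer a competency question
#'
#' Three benchmark queries scope the graph's content:
#' * `q1_effects_to_processes`: given observed adverse-effect tokens, which
#'   diseases/toxic processes may affect the subject? Ranked by shared-effect
#'   count (descending; ties broken by entity IRI).
#' * `q2_disease_to_pathways`: which biological processes or pathways are
#'   impacted by a disease? (reachable via `has_part` /
#'   `pathway_association`, with `is_a` inheritance).
#' * `q3_process_to_gene_products`: which gene products' functionality is
#'   hindered by a toxic process? (gene products participating in its
#'   affected processes).
#'
#' @param kg a linked, inferred `kgraph`.
#' @param kind one of `"q1_effects_to_processes"`, `"q2_disease_to_pathways"`,
#'   `"q3_process_to_gene_products"`.
#' @param params list: `effects` (character tokens) for q1; `disease` for q2;
#'   `process` for q3 (IRI, compact IRI, or label).
#' @return data frame of result rows (`entity`, `label`, and for q1
#'   `shared_count`). Unknown entities yield an empty result with a warning.
#' @export
competency_query <- function(kg,
                             kind = c("q1_effects_to_processes",
                                      "q2_disease_to_pathways",
                                      "q3_process_to_gene_products"),
                             params = list()) {
  kind <- match.arg(kind)
  q <- kg_quads(kg)
  lab <- q[q$predicate == kg_expand(RDFS_LABEL), , drop = FALSE]
  label_of <- setNames(lab$object, lab$subject)
  isa <- q[q$predicate == kg_expand(TXO_IS_A), , drop = FALSE]
  type_of <- function(iris, cls) {
    t <- q[q$predicate == kg_expand(RDF_TYPE) &
             q$object == kg_expand(cls), , drop = FALSE]
    iris[iris %in% t$subject]
  }

  if (kind == "q1_effects_to_processes") {
    effects <- normalize_label(params$effects %||% character(0))
    profiles <- effect_profiles(kg)
    rows <- lapply(profiles, function(pr) {
      data.frame(entity = pr$entity,
                 label = pr$label,
                 shared_count = length(intersect(effects, pr$effects)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[out$shared_count > 0, , drop = FALSE]
    out <- out[order(-out$shared_count, out$entity), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  start <- resolve_entity(kg, params[[if (kind == "q2_disease_to_pathways")
    "disease" else "process"]])
  if (!start %in% c(q$subject, q$object)) {
    warning("unknown entity: ", start, call. = FALSE)
    return(data.frame(entity = character(0), label = character(0)))
  }
  reach <- reachable(q, start, c(TXO_HAS_PART, TXO_PATHWAY), isa)
  if (kind == "q2_disease_to_pathways") {
    hits <- unique(c(type_of(reach, "txo:BiologicalProcess"),
                     type_of(reach, "txo:GoCamModel")))
  } else {
    pathways <- type_of(reach, "txo:BiologicalProcess")
    hits <- unique(q$object[q$subject %in% pathways &
                              q$predicate == kg_expand(TXO_PARTICIPANT)])
    hits <- type_of(hits, "txo:GeneProduct")
  }
  hits <- sort(hits)
  data.frame(entity = hits, label = unname(label_of[hits]),
             stringsAsFactors = FALSE)
}
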