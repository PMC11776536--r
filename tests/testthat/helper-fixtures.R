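# Shared helpers: tiny in-code fixtures for profile/record tests.

oecd408 <- function() profile_registry()$OECD_408

# a fully specified OECD 408 study record (scores 21 without defaults for
# all but the defaulted scheme fields)
complete_study <- function(study_id = "s1", compound_id = "c1", ...) {
  g <- generate_studies(generator_config(seed = 1L, n_studies = 1L, ...))
  rec <- g[[1]]
  rec$study_id <- study_id
  rec$compound_id <- compound_id
  rec
}

# drop named field paths from a study record
drop_fields <- function(rec, paths) {
  rec$fields <- rec$fields[!names(rec$fields) %in% paths]
  rec$provenance <- rec$provenance[!names(rec$provenance) %in% paths]
  rec
}

set_field <- function(rec, path, value) {
  rec$fields[[path]] <- value
  rec$provenance[[path]] <- "paper"
  rec
}

DOSEVOL_PATH <- "Test method/Test condition/dose-volume ml\\/kg bw"
ROUTE_PATH <- "Test method/Test condition/Oral administration/route"
HOMOG_PATH <- "Test method/Test substance/homogeneity and stability"

# a three-row mini dataset written to CSV files in a temp dir
write_mini_csvs <- function(dir,
                            compounds = NULL, effects = NULL,
                            studies = NULL, opinions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(compounds)) {
    compounds <- data.frame(compound_id = c("a", "b"),
                            ingredient_name = c("Compound A", "Compound B"))
  }
  write.csv(compounds, file.path(dir, "compounds.csv"), row.names = FALSE,
            na = "")
  if (!is.null(effects)) {
    write.csv(effects, file.path(dir, "effects.csv"), row.names = FALSE,
              na = "")
  }
  if (!is.null(studies)) {
    write.csv(studies, file.path(dir, "studies.csv"), row.names = FALSE,
              na = "")
  }
  if (!is.null(opinions)) {
    write.csv(opinions, file.path(dir, "opinions.csv"), row.names = FALSE,
              na = "")
  }
  dir
}

mini_ontology <- function() {
  read_turtle(system.file("extdata", "mini_ontology.ttl",
                          package = "toxinkg"))
}

built_kg <- function(dataset = load_screening_table(), min_shared = 2) {
  infer_affected_by(link_same_as(build_kg(dataset), mini_ontology()),
                    min_shared = min_shared)
}
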