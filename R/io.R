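#' Read an OMOP CONCEPT table
#'
#' Reads a delimited-text OMOP `CONCEPT` file into the concept catalogue used
#' throughout the pipeline. Column names are matched case-insensitively
#' against the OMOP CDM names; `standard_concept` (flagged `"S"` in OMOP) is
#' folded into a logical `is_standard` and defaults to `TRUE` when the column
#' is absent.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return A tibble with columns `concept_id`, `concept_name`,
#'   `vocabulary_id`, `concept_code`, `concept_class`, `is_standard`.
#' @export
read_concepts <- function(path, delim = ",") {
  df <- read_omop_table(path, delim)
  check_columns(
    df, c("concept_id", "concept_name", "vocabulary_id"), basename(path)
  )
  out <- tibble(
    concept_id = as.integer(df$concept_id),
    concept_name = as.character(df$concept_name),
    vocabulary_id = as.character(df$vocabulary_id),
    concept_code = as.character(col_or(df, "concept_code", rep("", nrow(df)))),
    concept_class = as.character(
      col_or(df, "concept_class", col_or(df, "concept_class_id", rep("", nrow(df))))
    ),
    is_standard = if ("is_standard" %in% names(df)) {
      as.logical(df$is_standard)
    } else if ("standard_concept" %in% names(df)) {
      !is.na(df$standard_concept) & df$standard_concept == "S"
    } else {
      rep(TRUE, nrow(df))
    }
  )
  out$concept_code[is.na(out$concept_code)] <- ""
  validate_concepts(out)
}

validate_concepts <- function(concepts) {
  dup <- concepts$concept_id[duplicated(concepts$concept_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate concept_id(s) in CONCEPT: %s",
      paste(sort(unique(dup)), collapse = ", ")
    ))
  }
  if (any(is.na(concepts$vocabulary_id) | concepts$vocabulary_id == "")) {
    abort("vocabulary_id must be non-empty for every concept")
  }
  concepts
}

#' Read an OMOP CONCEPT_RELATIONSHIP table
#'
#' Duplicate (subject, object, relationship) triples are collapsed to one
#' edge with a warning. When a concept catalogue is supplied, edges whose
#' endpoints do not resolve are kept but itemized in the `"unresolved"`
#' attribute so callers can decide whether to care.
#'
#' @param path Path to a delimited text file.
#' @param concepts Optional concept catalogue for endpoint validation.
#' @param delim Field delimiter.
#' @return A tibble of edges `subject_concept_id`, `object_concept_id`,
#'   `relationship_id`, with attribute `unresolved` (tibble of offending
#'   edges, possibly empty).
#' @export
read_relationships <- function(path, concepts = NULL, delim = ",") {
  df <- read_omop_table(path, delim)
  # OMOP names the endpoints concept_id_1 / concept_id_2
  if ("concept_id_1" %in% names(df) && !"subject_concept_id" %in% names(df)) {
    df$subject_concept_id <- df$concept_id_1
    df$object_concept_id <- df$concept_id_2
  }
  check_columns(
    df, c("subject_concept_id", "object_concept_id", "relationship_id"),
    basename(path)
  )
  edges <- tibble(
    subject_concept_id = as.integer(df$subject_concept_id),
    object_concept_id = as.integer(df$object_concept_id),
    relationship_id = as.character(df$relationship_id)
  )
  if (any(is.na(edges$subject_concept_id) | is.na(edges$object_concept_id))) {
    abort("both endpoint ids must be present on every relationship row")
  }
  n_raw <- nrow(edges)
  edges <- distinct(edges)
  if (nrow(edges) < n_raw) {
    warn(sprintf(
      "%d duplicate relationship triple(s) collapsed", n_raw - nrow(edges)
    ))
  }
  unresolved <- edges[0, ]
  if (!is.null(concepts)) {
    known <- concepts$concept_id
    bad <- !(edges$subject_concept_id %in% known) |
      !(edges$object_concept_id %in% known)
    unresolved <- edges[bad, ]
    if (nrow(unresolved) > 0) {
      warn(sprintf(
        "%d relationship edge(s) reference concepts absent from the catalogue",
        nrow(unresolved)
      ))
    }
  }
  attr(edges, "unresolved") <- unresolved
  edges
}

#' Read MEASUREMENT and OBSERVATION tables into one event store
#'
#' Unifies the two OMOP clinical tables into a single store of clinical
#' events, tagging each row with its `domain`. Per-row source labels
#' (`src_id`) are taken, in order of preference, from an extension side
#' table keyed on the event id, from an inline `src_id` column, or from
#' `config$default_src_id`. Coded values of 0 are normalised to `NA` (the
#' NONE sentinel: a row with no coded value).
#'
#' @param measurement_path,observation_path Paths to the base tables; either
#'   may be `NULL`.
#' @param measurement_ext_path,observation_ext_path Optional extension tables
#'   `(event_id, src_id)` keyed on the base table's id column.
#' @param concepts Optional concept catalogue; if supplied, events whose
#'   `element_concept_id` does not resolve are a hard error.
#' @param config Profiling configuration (for the default source label).
#' @param delim Field delimiter.
#' @return A tibble with columns `event_id`, `person_id`,
#'   `element_concept_id`, `domain`, `value_as_number`,
#'   `value_as_concept_id`, `src_id`; attribute `dropped` itemizes extension
#'   rows that referenced unknown event ids.
#' @export
read_clinical_events <- function(measurement_path = NULL,
                                 observation_path = NULL,
                                 measurement_ext_path = NULL,
                                 observation_ext_path = NULL,
                                 concepts = NULL,
                                 config = profile_config(),
                                 delim = ",") {
  config <- as_profile_config(config)
  parts <- list()
  dropped <- tibble(table = character(), event_id = integer())
  if (!is.null(measurement_path)) {
    m <- read_domain_table(measurement_path, "measurement", delim)
    res <- join_src(m, measurement_ext_path, "measurement_ext", delim, config)
    parts$measurement <- res$events
    dropped <- bind_rows(dropped, res$dropped)
  }
  if (!is.null(observation_path)) {
    o <- read_domain_table(observation_path, "observation", delim)
    res <- join_src(o, observation_ext_path, "observation_ext", delim, config)
    parts$observation <- res$events
    dropped <- bind_rows(dropped, res$dropped)
  }
  events <- bind_rows(parts)
  if (nrow(events) == 0 && length(parts) == 0) {
    abort("at least one of measurement_path / observation_path is required")
  }
  events <- normalize_events(events, concepts)
  attr(events, "dropped") <- dropped
  events
}

# Read one of MEASUREMENT / OBSERVATION, mapping OMOP column names onto the
# unified event schema.
read_domain_table <- function(path, domain, delim) {
  df <- read_omop_table(path, delim)
  id_col <- paste0(domain, "_id")
  concept_col <- paste0(domain, "_concept_id")
  if (!"event_id" %in% names(df) && id_col %in% names(df)) {
    df$event_id <- df[[id_col]]
  }
  if (!"element_concept_id" %in% names(df) && concept_col %in% names(df)) {
    df$element_concept_id <- df[[concept_col]]
  }
  check_columns(
    df, c("event_id", "person_id", "element_concept_id"), basename(path)
  )
  tibble(
    event_id = as.integer(df$event_id),
    person_id = as.integer(df$person_id),
    element_concept_id = as.integer(df$element_concept_id),
    domain = domain,
    value_as_number = as.numeric(
      col_or(df, "value_as_number", rep(NA_real_, nrow(df)))
    ),
    value_as_concept_id = as.integer(
      col_or(df, "value_as_concept_id", rep(NA_integer_, nrow(df)))
    ),
    src_id = as.character(col_or(df, "src_id", rep(NA_character_, nrow(df))))
  )
}

join_src <- function(events, ext_path, ext_name, delim, config) {
  dropped <- tibble(table = character(), event_id = integer())
  if (!is.null(ext_path)) {
    ext <- read_omop_table(ext_path, delim)
    id_col <- intersect(
      c("event_id", "measurement_id", "observation_id"), names(ext)
    )
    if (length(id_col) == 0 || !"src_id" %in% names(ext)) {
      abort(sprintf("%s must carry an event id column and src_id", ext_name))
    }
    ext <- tibble(
      event_id = as.integer(ext[[id_col[1]]]),
      ext_src_id = as.character(ext$src_id)
    )
    orphan <- !(ext$event_id %in% events$event_id)
    if (any(orphan)) {
      warn(sprintf(
        "%d %s row(s) reference unknown event ids and were dropped",
        sum(orphan), ext_name
      ))
      dropped <- tibble(table = ext_name, event_id = ext$event_id[orphan])
      ext <- ext[!orphan, ]
    }
    events <- left_join(events, ext, by = "event_id")
    events$src_id <- dplyr::coalesce(events$ext_src_id, events$src_id)
    events$ext_src_id <- NULL
  }
  events$src_id[is.na(events$src_id)] <- config$default_src_id
  list(events = events, dropped = dropped)
}

normalize_events <- function(events, concepts = NULL) {
  events$value_as_concept_id[is_none_value(events$value_as_concept_id)] <-
    NA_integer_
  if (!is.null(concepts)) {
    bad <- setdiff(events$element_concept_id, concepts$concept_id)
    if (length(bad) > 0) {
      abort(sprintf(
        "element_concept_id(s) not in the concept catalogue: %s",
        paste(sort(bad)[seq_len(min(5, length(bad)))], collapse = ", ")
      ))
    }
  }
  events
}

#' Read an initiative lookup table
#'
#' Maps a LOINC code to the data-collection initiative (PhenX, PROMIS, ...)
#' it was ingested from, mirroring LOINC's method/instrument metadata. Each
#' code must map to exactly one initiative.
#'
#' @param path Delimited text file with columns `loinc_code`, `initiative`.
#' @param delim Field delimiter.
#' @return A tibble `loinc_code`, `initiative`.
#' @export
read_initiative_lookup <- function(path, delim = ",") {
  df <- read_omop_table(path, delim)
  check_columns(df, c("loinc_code", "initiative"), basename(path))
  out <- distinct(tibble(
    loinc_code = as.character(df$loinc_code),
    initiative = as.character(df$initiative)
  ))
  dup <- out$loinc_code[duplicated(out$loinc_code)]
  if (length(dup) > 0) {
    abort(sprintf(
      "loinc_code(s) mapped to multiple initiatives: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  out
}

# Column accessor that does not rely on partial matching or tibble warnings.
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

# Shared reader: delimited text, header required, names lower-cased so OMOP
# columns match case-insensitively.
read_omop_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  df <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  names(df) <- tolower(names(df))
  df
}

#' Write a study bundle to a directory of delimited-text files
#'
#' Inverse of [read_study_bundle()]; used by the synthetic generator CLI and
#' handy for round-trip testing. Writes `concept.csv`,
#' `concept_relationship.csv`, `measurement.csv`, `observation.csv`,
#' `measurement_ext.csv`, `observation_ext.csv` and, when present,
#' `initiative_lookup.csv`.
#'
#' @param bundle A study bundle as produced by [generate_study()] or
#'   [make_reference_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  events <- bundle$events
  split_events <- function(dom) {
    ev <- filter(events, .data$domain == dom)
    base <- select(
      ev, "event_id", "person_id", "element_concept_id",
      "value_as_number", "value_as_concept_id"
    )
    ext <- select(ev, "event_id", "src_id")
    list(base = base, ext = ext)
  }
  m <- split_events("measurement")
  o <- split_events("observation")
  paths <- c(
    concept = file.path(dir, "concept.csv"),
    concept_relationship = file.path(dir, "concept_relationship.csv"),
    measurement = file.path(dir, "measurement.csv"),
    measurement_ext = file.path(dir, "measurement_ext.csv"),
    observation = file.path(dir, "observation.csv"),
    observation_ext = file.path(dir, "observation_ext.csv")
  )
  readr::write_csv(bundle$concepts, paths["concept"], progress = FALSE)
  readr::write_csv(bundle$relationships, paths["concept_relationship"], progress = FALSE)
  readr::write_csv(m$base, paths["measurement"], progress = FALSE)
  readr::write_csv(m$ext, paths["measurement_ext"], progress = FALSE)
  readr::write_csv(o$base, paths["observation"], progress = FALSE)
  readr::write_csv(o$ext, paths["observation_ext"], progress = FALSE)
  if (!is.null(bundle$initiative_lookup)) {
    paths <- c(paths, initiative_lookup = file.path(dir, "initiative_lookup.csv"))
    readr::write_csv(bundle$initiative_lookup, paths["initiative_lookup"], progress = FALSE)
  }
  invisible(paths)
}

#' Read a study bundle from a directory written by [write_study_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @param config Profiling configuration.
#' @return A list with `concepts`, `relationships`, `events` and (if the
#'   file exists) `initiative_lookup`.
#' @export
read_study_bundle <- function(dir, config = profile_config()) {
  concepts <- read_concepts(file.path(dir, "concept.csv"))
  relationships <- read_relationships(
    file.path(dir, "concept_relationship.csv"), concepts
  )
  events <- read_clinical_events(
    measurement_path = file.path(dir, "measurement.csv"),
    observation_path = file.path(dir, "observation.csv"),
    measurement_ext_path = file.path(dir, "measurement_ext.csv"),
    observation_ext_path = file.path(dir, "observation_ext.csv"),
    concepts = concepts, config = config
  )
  lookup_path <- file.path(dir, "initiative_lookup.csv")
  lookup <- if (file.exists(lookup_path)) read_initiative_lookup(lookup_path)
  list(
    concepts = concepts, relationships = relationships,
    events = events, initiative_lookup = lookup
  )
}
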