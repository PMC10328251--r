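#' Profiling configuration
#'
#' Bundles the tunable policy knobs of the audit: which vocabularies count as
#' study-custom (elements in them are UDEs), which `src_id` labels mark a row
#' as coming from a case report form or research visit, which value concepts
#' constitute answer avoidance, the minimum-participant export threshold, and
#' the relationship types walked when assigning elements to CRFs.
#'
#' Defaults mirror the All of Us registered-tier conventions: custom
#' vocabularies `PPI` and `AoU_General`; CRF source labels `PPI/PM` and
#' `PM/PPI` (both spellings occur in the wild); avoidance concepts 903096
#' (`PMI: Skip`, PPI) and 1177221 (`I prefer not to answer`, LOINC); and a
#' 20-participant small-cell suppression threshold.
#'
#' @param custom_vocabularies Character vector of `vocabulary_id`s whose
#'   elements are study-unique (UDEs).
#' @param crf_src_ids `src_id` labels attributed to the CRF/research-visit
#'   source; everything else is EHR.
#' @param avoidance_concept_ids Integer concept ids whose selection counts as
#'   answer avoidance. The first id is additionally treated as the "skip"
#'   concept for skip-specific tallies.
#' @param skip_concept_id Concept id of the skip value (defaults to the first
#'   avoidance id).
#' @param min_participants Minimum distinct participants an aggregate row
#'   must represent to be exportable (small-cell suppression; >= 1).
#' @param crf_relationship_ids Relationship types followed upward when
#'   assigning an element to its topic and CRF.
#' @param topic_class,module_class `concept_class` labels recognised as topic
#'   and CRF (module) concepts during traversal.
#' @param max_crf_depth Traversal depth bound; elements with no module within
#'   this many hops get `"No CRF Declared"`.
#' @param percent_decimals Decimals for narrative percentages (default 1).
#' @param table_percent_decimals Decimals for tabular percentages (default 2).
#' @param strict_src Logical; if `TRUE`, rows without an `src_id` are an
#'   error during source attribution, otherwise they fall back to EHR.
#' @param default_src_id Label assigned to rows with no source information at
#'   read time.
#' @return A list with class `"omop_profile_config"`.
#' @export
#' @examples
#' cfg <- profile_config(min_participants = 25)
#' cfg$min_participants
profile_config <- function(custom_vocabularies = c("PPI", "AoU_General"),
                           crf_src_ids = c("PPI/PM", "PM/PPI"),
                           avoidance_concept_ids = c(903096L, 1177221L),
                           skip_concept_id = avoidance_concept_ids[1],
                           min_participants = 20L,
                           crf_relationship_ids = c("Has parent", "Is a"),
                           topic_class = "Topic",
                           module_class = "Module",
                           max_crf_depth = 5L,
                           percent_decimals = 1L,
                           table_percent_decimals = 2L,
                           strict_src = FALSE,
                           default_src_id = "unknown") {
  cfg <- list(
    custom_vocabularies = as.character(custom_vocabularies),
    crf_src_ids = as.character(crf_src_ids),
    avoidance_concept_ids = as.integer(avoidance_concept_ids),
    skip_concept_id = as.integer(skip_concept_id),
    min_participants = as.integer(min_participants),
    crf_relationship_ids = as.character(crf_relationship_ids),
    topic_class = topic_class,
    module_class = module_class,
    max_crf_depth = as.integer(max_crf_depth),
    percent_decimals = as.integer(percent_decimals),
    table_percent_decimals = as.integer(table_percent_decimals),
    strict_src = isTRUE(strict_src),
    default_src_id = default_src_id
  )
  if (cfg$min_participants < 1L) {
    abort("min_participants must be >= 1")
  }
  if (cfg$percent_decimals < 0L || cfg$table_percent_decimals < 0L) {
    abort("percent decimals must be >= 0")
  }
  structure(cfg, class = "omop_profile_config")
}

#' Read a profiling configuration from a YAML or JSON file
#'
#' Any key of [profile_config()] may appear in the file; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path File path (YAML; JSON is valid YAML).
#' @return An `omop_profile_config` object.
#' @export
read_profile_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(profile_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown configuration key(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  do.call(profile_config, raw)
}

#' @export
print.omop_profile_config <- function(x, ...) {
  cat("<omop_profile_config>\n")
  cat("  custom vocabularies :", paste(x$custom_vocabularies, collapse = ", "), "\n")
  cat("  CRF src_ids         :", paste(x$crf_src_ids, collapse = ", "), "\n")
  cat("  avoidance concepts  :", paste(x$avoidance_concept_ids, collapse = ", "), "\n")
  cat("  min participants    :", x$min_participants, "\n")
  cat("  CRF relationships   :", paste(x$crf_relationship_ids, collapse = ", "), "\n")
  invisible(x)
}

as_profile_config <- function(config) {
  if (inherits(config, "omop_profile_config")) {
    return(config)
  }
  if (is.list(config)) {
    return(do.call(profile_config, config))
  }
  abort("`config` must be an omop_profile_config (see profile_config())")
}
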