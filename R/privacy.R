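#' Small-cell suppression of aggregate rows
#'
#' Removes rows representing fewer than `config$min_participants` distinct
#' participants before export. The threshold is inclusive: a row with
#' exactly the threshold count is kept. A table without the participant
#' column is a hard error — suppression must never silently pass.
#'
#' @param records Aggregate tibble exposing a distinct-participant count.
#' @param config Profiling configuration (`min_participants`).
#' @param participant_col Name of the participant-count column.
#' @return The filtered tibble, with attribute `"suppression"` (a one-row
#'   tibble: `rows_in`, `rows_out`, `rows_suppressed`, `threshold`)
#'   retrievable via [suppression_outcome()].
#' @export
#' @examples
#' tbl <- tibble::tibble(cell = 1:3, participant_count = c(19L, 20L, 21L))
#' kept <- suppress_small_cells(tbl, profile_config())
#' suppression_outcome(kept)
suppress_small_cells <- function(records, config = profile_config(),
                                 participant_col = "participant_count") {
  config <- as_profile_config(config)
  if (!participant_col %in% names(records)) {
    abort(sprintf(
      "suppression requires a `%s` column; refusing to pass the table through",
      participant_col
    ))
  }
  counts <- records[[participant_col]]
  if (any(is.na(counts))) {
    abort(sprintf("`%s` must not contain missing values", participant_col))
  }
  keep <- counts >= config$min_participants
  out <- records[keep, , drop = FALSE]
  attr(out, "suppression") <- tibble(
    rows_in = nrow(records),
    rows_out = nrow(out),
    rows_suppressed = nrow(records) - nrow(out),
    threshold = config$min_participants
  )
  out
}

#' Retrieve the suppression outcome of a filtered table
#'
#' @param x A tibble returned by [suppress_small_cells()].
#' @return One-row tibble `rows_in`, `rows_out`, `rows_suppressed`,
#'   `threshold`, or `NULL` if `x` was never suppressed.
#' @export
suppression_outcome <- function(x) {
  attr(x, "suppression", exact = TRUE)
}

#' Render the report bundle to delimited-text files
#'
#' Writes every profiled table as a CSV with deterministic ordering
#' (descending event count, ties by ascending concept id), so re-rendering
#' identical inputs yields byte-identical files. Tables that carry a
#' participant dimension have already been suppressed by [profile_study()];
#' tables without one (per-vocabulary counts, axis cells) are exempt and
#' flagged as such in `report_metadata.csv`.
#'
#' @param profile A profile object from [profile_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
render_reports <- function(profile, dir) {
  stopifnot(inherits(profile, "omop_cde_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flatten_sources <- function(tbl) {
    if ("sources" %in% names(tbl)) {
      tbl$sources <- purrr::map_chr(tbl$sources, paste, collapse = ";")
    }
    if ("value_vocabularies" %in% names(tbl)) {
      tbl$value_vocabularies <-
        purrr::map_chr(tbl$value_vocabularies, paste, collapse = ";")
    }
    tbl
  }
  tables <- list(
    element_dictionary = flatten_sources(profile$elements),
    elements_by_vocabulary = profile$summary$by_vocabulary,
    elements_by_origin = profile$summary$by_origin,
    elements_by_data_type = profile$summary$by_data_type,
    initiative_cdes = profile$summary$by_initiative,
    elements_by_crf = profile$summary$by_crf,
    element_values = profile$pairs,
    value_dictionary = profile$values,
    value_terminologies = profile$value_profile,
    answer_avoidance = profile$avoidance$summary,
    avoidance_usage = profile$avoidance$usage,
    concordance = flatten_sources(profile$concordance$records),
    concordance_summary = profile$concordance$summary,
    crossover = profile$crossover,
    axis_classification = profile$axes,
    headline = glance(profile)
  )
  paths <- character()
  for (name in names(tables)) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tables[[name]], path, progress = FALSE)
    paths[name] <- path
  }
  has_participants <- vapply(
    tables, function(t) "participant_count" %in% names(t), logical(1)
  )
  meta <- tibble(
    table = names(tables),
    participant_dimension = has_participants,
    suppression_applied = has_participants,
    suppression_threshold = profile$config$min_participants
  )
  meta_path <- file.path(dir, "report_metadata.csv")
  readr::write_csv(meta, meta_path, progress = FALSE)
  paths["report_metadata"] <- meta_path
  invisible(paths)
}
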