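#' Attribute events to the CRF or EHR source
#'
#' A row originates from a case report form (or research visit) when its
#' `src_id` is one of the configured CRF labels; every other label is an EHR
#' site. In strict mode a missing `src_id` is an error; otherwise such rows
#' fall back to EHR.
#'
#' @param events Event store.
#' @param config Profiling configuration (`crf_src_ids`, `strict_src`).
#' @return `events` with an added `source` column (`"CRF"` or `"EHR"`).
#' @export
attribute_source <- function(events, config = profile_config()) {
  config <- as_profile_config(config)
  check_columns(events, "src_id", "events")
  missing <- is.na(events$src_id) | events$src_id == ""
  if (any(missing)) {
    if (config$strict_src) {
      abort(sprintf("%d event(s) have no src_id (strict mode)", sum(missing)))
    }
    warn(sprintf(
      "%d event(s) have no src_id; attributed to EHR", sum(missing)
    ))
  }
  mutate(events, source = if_else(
    !missing & .data$src_id %in% config$crf_src_ids, "CRF", "EHR"
  ))
}

#' Find crossover elements (present in both CRF and EHR data)
#'
#' An element crosses over when it has at least one row from the CRF source
#' and at least one row from an EHR site. For each such element the CRF and
#' EHR row counts and the percentage of events originating from CRFs are
#' reported. Per-element source fractions for single-source elements
#' (trivially 0 or 100) are available in the `"all_elements"` attribute.
#'
#' @param events Event store.
#' @param config Profiling configuration.
#' @param concepts Optional concept catalogue to decorate the output with
#'   names and vocabularies.
#' @param total_participants Optional denominator for `pct_of_participants`;
#'   defaults to the distinct persons in `events`.
#' @return Tibble `element_concept_id`, (`concept_name`, `vocabulary_id`,
#'   `concept_code` when `concepts` given), `crf_event_count`,
#'   `ehr_event_count`, `event_count`, `participant_count`,
#'   `pct_of_participants`, `pct_from_crf`, ordered by descending event
#'   count.
#' @export
find_crossover_elements <- function(events, config = profile_config(),
                                    concepts = NULL,
                                    total_participants = NULL) {
  config <- as_profile_config(config)
  attributed <- if ("source" %in% names(events)) {
    events
  } else {
    attribute_source(events, config)
  }
  denom <- total_participants %||% n_distinct(attributed$person_id)
  per <- attributed |>
    group_by(element_concept_id = .data$element_concept_id) |>
    summarise(
      crf_event_count = sum(.data$source == "CRF"),
      ehr_event_count = sum(.data$source == "EHR"),
      participant_count = n_distinct(.data$person_id),
      .groups = "drop"
    ) |>
    mutate(
      event_count = .data$crf_event_count + .data$ehr_event_count,
      pct_of_participants = pct_of(
        .data$participant_count, denom, config$table_percent_decimals
      ),
      pct_from_crf = pct_of(
        .data$crf_event_count, .data$event_count, config$percent_decimals
      )
    )
  if (!is.null(concepts)) {
    per <- left_join(
      per,
      select(
        concepts, element_concept_id = "concept_id",
        "concept_name", "vocabulary_id", "concept_code"
      ),
      by = "element_concept_id"
    ) |>
      select(
        "element_concept_id", "concept_name", "vocabulary_id",
        "concept_code", "crf_event_count", "ehr_event_count",
        "event_count", "participant_count", "pct_of_participants",
        "pct_from_crf"
      )
  }
  per <- arrange(per, desc(.data$event_count), .data$element_concept_id)
  out <- filter(per, .data$crf_event_count > 0, .data$ehr_event_count > 0)
  attr(out, "all_elements") <- per
  out
}

#' Two-axis classification of CDEs (origin x ingestion)
#'
#' Partitions CDEs along an origin axis (O1: routine-healthcare elements,
#' O2: research-initiative elements) and a terminology-ingestion axis (T1:
#' ingested into a routine healthcare terminology, T2: not ingested). Every
#' CDE observed in study data is by construction T1-ingested; CDEs also seen
#' in routine healthcare data (the supplied `healthcare_elements`, or
#' failing that the crossover list) are O1, the rest O2. The
#' O2-research-T2-non-ingested cell is emitted with its (structurally zero)
#' count. UDEs sit outside the classification and are reported separately in
#' the `"ude_count"` attribute.
#'
#' @param element_records Element dictionary.
#' @param crossover Crossover table from [find_crossover_elements()].
#' @param healthcare_elements Optional integer vector of concept ids known
#'   to occur in routine healthcare data; defaults to the crossover
#'   elements.
#' @return Tibble `origin`, `ingestion`, `element_count` with attribute
#'   `ude_count`.
#' @export
classify_axes <- function(element_records, crossover,
                          healthcare_elements = NULL) {
  cdes <- filter(element_records, .data$origin_class == "CDE")
  healthcare <- healthcare_elements %||% crossover$element_concept_id
  o1 <- sum(cdes$concept_id %in% healthcare)
  cells <- tibble(
    origin = c("O1-healthcare", "O2-research", "O2-research"),
    ingestion = c("T1-ingested", "T1-ingested", "T2-non-ingested"),
    element_count = c(o1, nrow(cdes) - o1, 0L)
  )
  attr(cells, "ude_count") <- sum(element_records$origin_class == "UDE")
  cells
}
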