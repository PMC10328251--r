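#' Build the element-value combination table
#'
#' One row per distinct (categorical element, value) pair observed in the
#' event store. Rows without a coded value are tallied under the NONE
#' sentinel (`value_concept_id = NA`, vocabulary `"None"`). The percentage
#' denominator for each pair is the element's total categorical rows,
#' including avoidance and NONE rows. Coded rows of numeric elements are
#' excluded from the pair table but tallied in the `"numeric_coded"`
#' attribute for diagnostics.
#'
#' @param events Event store.
#' @param concepts Concept catalogue.
#' @param element_records Element dictionary (supplies each element's data
#'   type).
#' @param config Profiling configuration.
#' @return Tibble with `element_concept_id`, `element_name`,
#'   `element_vocabulary`, `value_concept_id`, `value_name`,
#'   `value_vocabulary`, `count`, `participant_count`, `pct_of_element`,
#'   ordered by element then descending count.
#' @export
build_element_value_table <- function(events, concepts, element_records,
                                      config = profile_config()) {
  config <- as_profile_config(config)
  categorical <- filter(element_records, .data$data_type == "categorical")
  ev <- filter(events, .data$element_concept_id %in% categorical$concept_id)

  numeric_ids <- filter(element_records, .data$data_type == "numeric")$concept_id
  numeric_coded <- events |>
    filter(
      .data$element_concept_id %in% numeric_ids,
      !is.na(.data$value_as_concept_id)
    ) |>
    count(.data$element_concept_id, .data$value_as_concept_id, name = "count")

  pairs <- ev |>
    group_by(
      element_concept_id = .data$element_concept_id,
      value_concept_id = .data$value_as_concept_id
    ) |>
    summarise(
      count = n(),
      participant_count = n_distinct(.data$person_id),
      .groups = "drop_last"
    ) |>
    mutate(
      pct_of_element = pct_of(
        .data$count, sum(.data$count), config$percent_decimals
      )
    ) |>
    ungroup()

  concept_names <- stats::setNames(concepts$concept_name, concepts$concept_id)
  concept_vocab <- stats::setNames(concepts$vocabulary_id, concepts$concept_id)
  pairs <- pairs |>
    mutate(
      element_name = unname(concept_names[as.character(.data$element_concept_id)]),
      element_vocabulary = unname(concept_vocab[as.character(.data$element_concept_id)]),
      value_name = if_else(
        is.na(.data$value_concept_id), none_label(),
        unname(concept_names[as.character(.data$value_concept_id)])
      ),
      value_vocabulary = if_else(
        is.na(.data$value_concept_id), none_label(),
        unname(concept_vocab[as.character(.data$value_concept_id)])
      )
    ) |>
    select(
      "element_concept_id", "element_name", "element_vocabulary",
      "value_concept_id", "value_name", "value_vocabulary",
      "count", "participant_count", "pct_of_element"
    ) |>
    arrange(
      .data$element_concept_id, desc(.data$count), .data$value_concept_id
    )
  attr(pairs, "numeric_coded") <- numeric_coded
  pairs
}

#' Build the permissible-value dictionary
#'
#' Aggregates the pair table per distinct value concept: how many elements
#' use the value, its total usage volume, its vocabulary, and whether that
#' vocabulary is standardized (outside the study-custom set). The NONE
#' sentinel is reported under vocabulary `"None"` and is never standardized.
#' Value identity is by concept id, not display name: the same label (e.g.
#' "No") may exist in several terminologies.
#'
#' @param pairs Pair table from [build_element_value_table()].
#' @param concepts Concept catalogue.
#' @param config Profiling configuration.
#' @return Tibble `value_concept_id`, `value_name`, `vocabulary_id`,
#'   `n_elements`, `total_count`, `standardized`, ordered by descending
#'   usage.
#' @export
build_value_dictionary <- function(pairs, concepts,
                                   config = profile_config()) {
  config <- as_profile_config(config)
  pairs |>
    group_by(
      .data$value_concept_id, .data$value_name,
      vocabulary_id = .data$value_vocabulary
    ) |>
    summarise(
      n_elements = n_distinct(.data$element_concept_id),
      total_count = sum(.data$count),
      .groups = "drop"
    ) |>
    # standardized is defined purely by vocabulary membership: anything
    # outside the study-custom set counts, including the NONE sentinel row
    # (which is how the published standardized-value total is reckoned)
    mutate(
      standardized = !(.data$vocabulary_id %in% config$custom_vocabularies)
    ) |>
    arrange(desc(.data$total_count), .data$value_concept_id)
}

#' Quantify answer avoidance
#'
#' Flags, per categorical element, whether its observed value set offers a
#' skip value and, more broadly, any avoidance value ("skip" or "prefer not
#' to answer"), and totals how often each avoidance concept was used. The
#' NONE sentinel never counts as avoidance.
#'
#' @param pairs Pair table.
#' @param config Profiling configuration (avoidance concept ids; the first
#'   is the skip concept).
#' @param n_elements_total Denominator for the summary percentages; defaults
#'   to the number of distinct elements in `pairs`. Pass the full element
#'   count to express shares of all elements, numeric included.
#' @return List with `elements` (per-element flags), `summary` (one row) and
#'   `usage` (rows per avoidance concept).
#' @export
detect_answer_avoidance <- function(pairs, config = profile_config(),
                                    n_elements_total = NULL) {
  config <- as_profile_config(config)
  flags <- pairs |>
    group_by(.data$element_concept_id) |>
    summarise(
      skip_enabled = any(
        .data$value_concept_id %in% config$skip_concept_id
      ),
      avoidance_enabled = any(
        .data$value_concept_id %in% config$avoidance_concept_ids
      ),
      .groups = "drop"
    )
  denom <- n_elements_total %||% nrow(flags)
  usage <- pairs |>
    filter(.data$value_concept_id %in% config$avoidance_concept_ids) |>
    group_by(
      value_concept_id = .data$value_concept_id,
      value_name = .data$value_name
    ) |>
    summarise(
      n_elements = n_distinct(.data$element_concept_id),
      total_count = sum(.data$count),
      .groups = "drop"
    )
  summary <- tibble(
    n_elements = denom,
    skip_enabled = sum(flags$skip_enabled),
    pct_skip_enabled = pct_of(
      sum(flags$skip_enabled), denom, config$percent_decimals
    ),
    avoidance_enabled = sum(flags$avoidance_enabled),
    pct_avoidance_enabled = pct_of(
      sum(flags$avoidance_enabled), denom, config$percent_decimals
    )
  )
  list(elements = flags, summary = summary, usage = usage)
}

#' Per-vocabulary profile of value usage
#'
#' For each value terminology: how many distinct values it contributes, the
#' share of all distinct values, and how many elements have at least one
#' value from it (an element counts once per vocabulary).
#'
#' @param values Value dictionary from [build_value_dictionary()].
#' @param pairs Pair table.
#' @param config Profiling configuration.
#' @param n_elements_total Denominator for the element-share column;
#'   defaults to the distinct elements in `pairs`.
#' @return Tibble `vocabulary_id`, `distinct_values`, `pct_of_values`,
#'   `elements`, `pct_of_elements`.
#' @export
value_terminology_profile <- function(values, pairs,
                                      config = profile_config(),
                                      n_elements_total = NULL) {
  config <- as_profile_config(config)
  td <- config$table_percent_decimals
  n_values <- nrow(values)
  denom <- n_elements_total %||% n_distinct(pairs$element_concept_id)
  per_vocab_values <- values |>
    count(.data$vocabulary_id, name = "distinct_values")
  per_vocab_elements <- pairs |>
    distinct(.data$value_vocabulary, .data$element_concept_id) |>
    count(vocabulary_id = .data$value_vocabulary, name = "elements")
  per_vocab_values |>
    left_join(per_vocab_elements, by = "vocabulary_id") |>
    mutate(
      elements = dplyr::coalesce(.data$elements, 0L),
      pct_of_values = pct_of(.data$distinct_values, n_values, td),
      pct_of_elements = pct_of(.data$elements, denom, td)
    ) |>
    select(
      "vocabulary_id", "distinct_values", "pct_of_values",
      "elements", "pct_of_elements"
    ) |>
    arrange(desc(.data$distinct_values), .data$vocabulary_id)
}

#' Element/value terminology concordance
#'
#' Compares each categorical element's terminology with the terminologies of
#' its observed values (NONE rows excluded): `same-terminology-only` when
#' all values come from one terminology and it is the element's own,
#' `different-terminology-only` when all values come from one terminology
#' that differs from the element's, and `mixed` when values span two or more
#' terminologies. The summary additionally counts UDEs with at least one /
#' only standardized values, UDEs with only custom values, and CDEs with at
#' least one custom value.
#'
#' @param element_records Element dictionary.
#' @param pairs Pair table.
#' @param config Profiling configuration.
#' @return List with `records` (per-element class and value vocabulary set)
#'   and `summary` (one row of counts).
#' @export
element_value_concordance <- function(element_records, pairs,
                                      config = profile_config()) {
  config <- as_profile_config(config)
  real <- filter(pairs, !is.na(.data$value_concept_id))
  vocab_sets <- real |>
    distinct(.data$element_concept_id, .data$value_vocabulary) |>
    group_by(.data$element_concept_id) |>
    summarise(
      value_vocabularies = list(sort(unique(.data$value_vocabulary))),
      .groups = "drop"
    )
  categorical <- filter(element_records, .data$data_type == "categorical")
  records <- categorical |>
    select(
      element_concept_id = "concept_id", "vocabulary_id", "origin_class"
    ) |>
    left_join(vocab_sets, by = "element_concept_id") |>
    mutate(
      value_vocabularies = purrr::map(
        .data$value_vocabularies, ~ .x %||% character()
      ),
      n_vocabs = purrr::map_int(.data$value_vocabularies, length),
      concordance_class = dplyr::case_when(
        .data$n_vocabs >= 2 ~ "mixed",
        .data$n_vocabs == 1 & purrr::map2_lgl(
          .data$value_vocabularies, .data$vocabulary_id, ~ .y %in% .x
        ) ~ "same-terminology-only",
        TRUE ~ "different-terminology-only"
      )
    )
  std <- function(vocabs) {
    setdiff(vocabs, config$custom_vocabularies)
  }
  records <- records |>
    mutate(
      has_standardized = purrr::map_lgl(
        .data$value_vocabularies, ~ length(std(.x)) > 0
      ),
      has_custom = purrr::map_lgl(
        .data$value_vocabularies,
        ~ length(intersect(.x, config$custom_vocabularies)) > 0
      )
    )
  is_ude <- records$origin_class == "UDE"
  has_values <- records$n_vocabs > 0
  summary <- tibble(
    categorical_elements = nrow(records),
    same_terminology_only = sum(records$concordance_class == "same-terminology-only"),
    different_terminology_only = sum(records$concordance_class == "different-terminology-only"),
    mixed = sum(records$concordance_class == "mixed"),
    ude_with_standardized_values = sum(is_ude & records$has_standardized),
    ude_only_standardized_values = sum(
      is_ude & has_values & records$has_standardized & !records$has_custom
    ),
    ude_only_custom_values = sum(
      is_ude & has_values & records$has_custom & !records$has_standardized
    ),
    cde_with_custom_values = sum(!is_ude & records$has_custom)
  )
  list(
    records = select(
      records, "element_concept_id", "vocabulary_id", "origin_class",
      "concordance_class", "value_vocabularies"
    ),
    summary = summary
  )
}
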