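#' Classify element origin: CDE or UDE
#'
#' An element is a common data element (CDE) when its concept lives in an
#' established terminology, and a unique data element (UDE) when it was
#' minted in one of the study's custom vocabularies.
#'
#' @param vocabulary_id Character vector of vocabulary ids.
#' @param config Profiling configuration (supplies the custom set).
#' @return Character vector, `"CDE"` or `"UDE"`.
#' @export
#' @examples
#' classify_element_origin(c("LOINC", "PPI"), profile_config())
classify_element_origin <- function(vocabulary_id, config = profile_config()) {
  config <- as_profile_config(config)
  if (any(is.na(vocabulary_id) | vocabulary_id == "")) {
    abort("vocabulary_id must be non-empty")
  }
  if_else(vocabulary_id %in% config$custom_vocabularies, "UDE", "CDE")
}

#' Classify an element's data type from its rows
#'
#' An element is numeric when strictly more than half of its data rows carry
#' a `value_as_number`; otherwise it is categorical. The inequality is
#' strict: exactly half numeric is categorical.
#'
#' @param events_for_element Tibble of clinical events, all for one element;
#'   must be non-empty.
#' @return `"numeric"` or `"categorical"`.
#' @export
classify_data_type <- function(events_for_element) {
  check_columns(events_for_element, "value_as_number", "events_for_element")
  n <- nrow(events_for_element)
  if (n == 0) {
    abort("an element cannot exist without data rows")
  }
  if (sum(!is.na(events_for_element$value_as_number)) / n > 0.5) {
    "numeric"
  } else {
    "categorical"
  }
}

#' Map CDEs to their data-collection initiative
#'
#' Joins the initiative lookup (LOINC code -> instrument/initiative, the
#' analogue of LOINC's method type) onto LOINC CDEs. UDEs and non-LOINC CDEs
#' never receive an initiative.
#'
#' @param elements Tibble with at least `vocabulary_id`, `concept_code`,
#'   `origin_class`.
#' @param lookup Initiative lookup (`loinc_code`, `initiative`) or `NULL`.
#' @return `elements` with an `initiative` column (`NA` where none applies).
#' @export
map_initiative <- function(elements, lookup = NULL) {
  if (is.null(lookup) || nrow(lookup) == 0) {
    return(mutate(elements, initiative = NA_character_))
  }
  out <- left_join(
    elements, rename(lookup, concept_code = "loinc_code"),
    by = "concept_code"
  )
  mutate(out, initiative = if_else(
    .data$origin_class == "CDE" & .data$vocabulary_id == "LOINC",
    .data$initiative, NA_character_
  ))
}

#' Assign elements to their topic and case report form
#'
#' Walks the concept-relationship hierarchy upward from each element along
#' the configured relationship types. The nearest reachable concept of the
#' topic class is the element's topic; the nearest of the module class is
#' its CRF. Ties at equal depth resolve to the lexicographically smallest
#' concept name and are flagged in the `ambiguous` column. Elements with no
#' module within `config$max_crf_depth` hops get `"No CRF Declared"`.
#'
#' @param element_ids Integer vector of element concept ids.
#' @param relationships Edge tibble (`subject_concept_id`,
#'   `object_concept_id`, `relationship_id`).
#' @param concepts Concept catalogue (supplies class and name).
#' @param config Profiling configuration.
#' @return Tibble `element_concept_id`, `topic`, `crf`, `ambiguous`.
#' @export
assign_crf <- function(element_ids, relationships, concepts,
                       config = profile_config()) {
  config <- as_profile_config(config)
  no_crf <- "No CRF Declared"
  element_ids <- unique(as.integer(element_ids))
  if (is.null(relationships) || nrow(relationships) == 0) {
    return(tibble(
      element_concept_id = element_ids,
      topic = NA_character_, crf = no_crf, ambiguous = FALSE
    ))
  }
  edges <- filter(
    relationships, .data$relationship_id %in% config$crf_relationship_ids
  )
  assert_acyclic(edges)
  adj <- split(edges$object_concept_id, edges$subject_concept_id)
  cls <- stats::setNames(concepts$concept_class, concepts$concept_id)
  nm <- stats::setNames(concepts$concept_name, concepts$concept_id)

  one <- function(id) {
    topic <- NA_character_
    crf <- NA_character_
    ambiguous <- FALSE
    frontier <- id
    seen <- id
    for (depth in seq_len(config$max_crf_depth)) {
      nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (length(nxt) == 0) break
      classes <- cls[as.character(nxt)]
      if (is.na(topic)) {
        hits <- nxt[!is.na(classes) & classes == config$topic_class]
        if (length(hits) > 0) {
          topic <- sort(nm[as.character(hits)])[[1]]
        }
      }
      if (is.na(crf)) {
        hits <- nxt[!is.na(classes) & classes == config$module_class]
        if (length(hits) > 0) {
          if (length(hits) > 1) ambiguous <- TRUE
          crf <- sort(nm[as.character(hits)])[[1]]
        }
      }
      if (!is.na(topic) && !is.na(crf)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    tibble(
      element_concept_id = id, topic = topic,
      crf = if (is.na(crf)) no_crf else crf, ambiguous = ambiguous
    )
  }
  purrr::map_dfr(element_ids, one)
}

# Kahn's algorithm over the CRF-relationship subgraph; an unshrinkable core
# means a cycle, which would make "upward" ill-defined.
assert_acyclic <- function(edges) {
  if (nrow(edges) == 0) {
    return(invisible(TRUE))
  }
  ed <- distinct(select(edges, "subject_concept_id", "object_concept_id"))
  repeat {
    sinks <- setdiff(ed$object_concept_id, ed$subject_concept_id)
    keep <- !(ed$object_concept_id %in% sinks)
    if (all(keep)) break
    ed <- ed[keep, ]
    if (nrow(ed) == 0) {
      return(invisible(TRUE))
    }
  }
  cyc <- sort(unique(c(ed$subject_concept_id, ed$object_concept_id)))
  abort(sprintf(
    "cycle detected in the CRF hierarchy involving concept(s): %s",
    paste(cyc, collapse = " -> ")
  ))
}

#' Build the data-element dictionary
#'
#' One row per distinct element concept observed in the event store, with
#' usage volume (`event_count`), participant coverage (`participant_count`,
#' `participant_pct`), CDE/UDE origin, the majority-rule data type,
#' initiative provenance (for LOINC CDEs) and CRF assignment (when a
#' relationship graph is supplied).
#'
#' @param events Event store from [read_clinical_events()] or a generator.
#' @param concepts Concept catalogue.
#' @param config Profiling configuration.
#' @param total_participants Optional denominator for `participant_pct`;
#'   defaults to the number of distinct persons in `events`.
#' @param relationships Optional relationship edges for CRF assignment.
#' @param initiative_lookup Optional initiative lookup.
#' @return Tibble, one row per element, ordered by descending `event_count`
#'   then ascending `concept_id`.
#' @export
build_element_dictionary <- function(events, concepts,
                                     config = profile_config(),
                                     total_participants = NULL,
                                     relationships = NULL,
                                     initiative_lookup = NULL) {
  config <- as_profile_config(config)
  check_columns(
    events,
    c("person_id", "element_concept_id", "value_as_number", "src_id"),
    "events"
  )
  if (nrow(events) == 0) {
    return(tibble(
      concept_id = integer(), concept_name = character(),
      vocabulary_id = character(), concept_code = character(),
      event_count = integer(), participant_count = integer(),
      participant_pct = numeric(), origin_class = character(),
      data_type = character(), initiative = character(),
      topic = character(), crf = character(), sources = list()
    ))
  }
  bad <- setdiff(events$element_concept_id, concepts$concept_id)
  if (length(bad) > 0) {
    abort(sprintf(
      "events reference element concept(s) missing from the catalogue: %s",
      paste(sort(bad)[seq_len(min(5, length(bad)))], collapse = ", ")
    ))
  }
  denom <- total_participants %||% n_distinct(events$person_id)

  per <- events |>
    group_by(concept_id = .data$element_concept_id) |>
    summarise(
      event_count = n(),
      participant_count = n_distinct(.data$person_id),
      n_numeric = sum(!is.na(.data$value_as_number)),
      sources = list(sort(unique(.data$src_id))),
      .groups = "drop"
    ) |>
    mutate(
      participant_pct = pct_of(
        .data$participant_count, denom, config$percent_decimals
      ),
      data_type = if_else(
        .data$n_numeric / .data$event_count > 0.5, "numeric", "categorical"
      )
    ) |>
    select(-"n_numeric")

  dict <- per |>
    left_join(
      select(
        concepts, "concept_id", "concept_name", "vocabulary_id", "concept_code"
      ),
      by = "concept_id"
    ) |>
    mutate(origin_class = classify_element_origin(.data$vocabulary_id, config))

  dict <- map_initiative(dict, initiative_lookup)
  crf <- assign_crf(dict$concept_id, relationships, concepts, config)
  dict <- left_join(
    dict, rename(crf, concept_id = "element_concept_id"),
    by = "concept_id"
  )
  dict |>
    select(
      "concept_id", "concept_name", "vocabulary_id", "concept_code",
      "event_count", "participant_count", "participant_pct",
      "origin_class", "data_type", "initiative", "topic", "crf",
      "ambiguous", "sources"
    ) |>
    arrange(desc(.data$event_count), .data$concept_id)
}

#' Summarise the element dictionary
#'
#' Marginal tables over the element dictionary: totals, counts and
#' percentages per vocabulary, per origin class (CDE/UDE), per data type,
#' per initiative, and per CRF (elements, CDEs, UDEs, percent of total).
#' Narrative percentages use `config$percent_decimals`; per-CRF table
#' percentages use `config$table_percent_decimals`.
#'
#' @param records Element dictionary from [build_element_dictionary()].
#' @param config Profiling configuration.
#' @return A list of tibbles: `totals`, `by_vocabulary`, `by_origin`,
#'   `by_data_type`, `by_initiative`, `by_crf`.
#' @export
summarize_dictionary <- function(records, config = profile_config()) {
  config <- as_profile_config(config)
  if (nrow(records) == 0) {
    abort("cannot summarise an empty element dictionary")
  }
  total <- nrow(records)
  nd <- config$percent_decimals
  td <- config$table_percent_decimals

  by_vocab <- records |>
    count(.data$vocabulary_id, name = "elements") |>
    mutate(pct = pct_of(.data$elements, total, nd)) |>
    arrange(desc(.data$elements), .data$vocabulary_id)
  by_origin <- records |>
    count(.data$origin_class, name = "elements") |>
    mutate(pct = pct_of(.data$elements, total, nd)) |>
    arrange(.data$origin_class)
  by_type <- records |>
    count(.data$data_type, name = "elements") |>
    mutate(pct = pct_of(.data$elements, total, nd)) |>
    arrange(.data$data_type)
  n_cde <- sum(records$origin_class == "CDE")
  with_init <- filter(records, !is.na(.data$initiative))
  by_init <- with_init |>
    count(.data$initiative, name = "elements") |>
    mutate(pct_of_initiative_cdes = pct_of(.data$elements, nrow(with_init), td)) |>
    arrange(desc(.data$elements), .data$initiative)
  by_crf <- records |>
    group_by(.data$crf) |>
    summarise(
      elements = n(),
      udes = sum(.data$origin_class == "UDE"),
      cdes = sum(.data$origin_class == "CDE"),
      .groups = "drop"
    ) |>
    mutate(pct_of_total = pct_of(.data$elements, total, td)) |>
    select("crf", "elements", "pct_of_total", "udes", "cdes") |>
    arrange(desc(.data$elements), .data$crf)

  list(
    totals = tibble(
      total_elements = total,
      cde_elements = n_cde,
      ude_elements = total - n_cde,
      pct_cde = pct_of(n_cde, total, nd),
      pct_ude = pct_of(total - n_cde, total, nd),
      numeric_elements = sum(records$data_type == "numeric"),
      categorical_elements = sum(records$data_type == "categorical"),
      initiative_cdes = nrow(with_init),
      pct_initiative_cdes = pct_of(nrow(with_init), n_cde, nd)
    ),
    by_vocabulary = by_vocab,
    by_origin = by_origin,
    by_data_type = by_type,
    by_initiative = by_init,
    by_crf = by_crf
  )
}
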