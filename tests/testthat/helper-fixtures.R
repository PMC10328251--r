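# Shared fixtures. The reference study takes a few seconds to build and
# profile, so it is memoised for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

reference_profile <- function() {
  if (is.null(.fixture_cache$ref_profile)) {
    .fixture_cache$ref_study <- make_reference_study()
    .fixture_cache$ref_profile <- profile_bundle(.fixture_cache$ref_study)
  }
  .fixture_cache$ref_profile
}

reference_study_cached <- function() {
  if (is.null(.fixture_cache$ref_study)) {
    .fixture_cache$ref_study <- make_reference_study()
  }
  .fixture_cache$ref_study
}

# Minimal in-memory event store builder.
make_events <- function(element, person, value_num = NA_real_,
                        value_concept = NA_integer_, src = "PPI/PM",
                        domain = "observation") {
  n <- max(length(element), length(person))
  tibble::tibble(
    event_id = seq_len(n),
    person_id = rep_len(person, n),
    element_concept_id = rep_len(element, n),
    domain = rep_len(domain, n),
    value_as_number = rep_len(value_num, n),
    value_as_concept_id = rep_len(value_concept, n),
    src_id = rep_len(src, n)
  )
}

# Concept catalogue builder: one row per id, vocabulary cycled.
make_concepts <- function(ids, vocab = "PPI", class = "Question",
                          name = NULL, code = NULL) {
  tibble::tibble(
    concept_id = as.integer(ids),
    concept_name = name %||% sprintf("Concept %d", ids),
    vocabulary_id = rep_len(vocab, length(ids)),
    concept_code = code %||% sprintf("C%d", ids),
    concept_class = rep_len(class, length(ids)),
    is_standard = TRUE
  )
}

`%||%` <- rlang::`%||%`

# Independent recount oracle: per-element statistics computed row by row
# with base R only, no dplyr grouping.
recount_elements <- function(events) {
  ids <- sort(unique(events$element_concept_id))
  do.call(rbind, lapply(ids, function(id) {
    sub <- events[events$element_concept_id == id, ]
    data.frame(
      concept_id = id,
      event_count = nrow(sub),
      participant_count = length(unique(sub$person_id)),
      n_numeric = sum(!is.na(sub$value_as_number))
    )
  }))
}
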