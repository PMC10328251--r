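#' Profile an OMOP study: the full element/value/crossover audit
#'
#' Runs the whole audit over an event store: source attribution, the
#' data-element dictionary (usage, CDE/UDE origin, data type, initiative,
#' CRF), the permissible-value dictionary and element-value combinations,
#' answer avoidance, value-terminology concordance, CRF/EHR crossover, the
#' two-axis CDE classification, and small-cell suppression of every
#' participant-bearing aggregate.
#'
#' With `scope = "crf"` (the default, mirroring how a survey audit is
#' scoped) the element universe is restricted to elements with at least one
#' CRF-attributed row; their usage counts still include EHR rows, while the
#' value-level analysis uses only CRF rows. With `scope = "all"` every
#' element in the store is profiled and all rows feed the value analysis.
#'
#' @param events Event store from [read_clinical_events()] or a generator
#'   bundle.
#' @param concepts Concept catalogue.
#' @param relationships Optional relationship edges (CRF assignment).
#' @param initiative_lookup Optional initiative lookup.
#' @param config Profiling configuration.
#' @param total_participants Optional participant denominator overriding the
#'   distinct-person count of the store.
#' @param scope `"crf"` or `"all"`, see above.
#' @param suppress Apply small-cell suppression to exportable tables
#'   (default `TRUE`).
#' @param healthcare_elements Optional concept ids known from routine
#'   healthcare data, for the two-axis classification.
#' @return An object of class `"omop_cde_profile"`: a list with `elements`,
#'   `summary`, `pairs`, `values`, `value_profile`, `avoidance`,
#'   `concordance`, `crossover`, `axes`, `suppression`, `config`,
#'   `total_participants`.
#' @export
#' @examples
#' study <- generate_study(generator_config(seed = 7, n_elements = 12))
#' prof <- profile_study(
#'   study$events, study$concepts,
#'   relationships = study$relationships,
#'   initiative_lookup = study$initiative_lookup
#' )
#' glance(prof)
profile_study <- function(events, concepts,
                          relationships = NULL,
                          initiative_lookup = NULL,
                          config = profile_config(),
                          total_participants = NULL,
                          scope = c("crf", "all"),
                          suppress = TRUE,
                          healthcare_elements = NULL) {
  config <- as_profile_config(config)
  scope <- match.arg(scope)
  events <- normalize_events(events)
  attributed <- attribute_source(events, config)
  if (scope == "crf") {
    crf_elements <- unique(
      attributed$element_concept_id[attributed$source == "CRF"]
    )
    attributed <- filter(
      attributed, .data$element_concept_id %in% crf_elements
    )
    value_events <- filter(attributed, .data$source == "CRF")
  } else {
    value_events <- attributed
  }

  elements <- build_element_dictionary(
    attributed, concepts,
    config = config,
    total_participants = total_participants,
    relationships = relationships,
    initiative_lookup = initiative_lookup
  )
  suppression <- list()
  if (suppress) {
    elements <- suppress_small_cells(elements, config)
    suppression$elements <- suppression_outcome(elements)
    value_events <- filter(
      value_events, .data$element_concept_id %in% elements$concept_id
    )
    attributed <- filter(
      attributed, .data$element_concept_id %in% elements$concept_id
    )
  }
  if (nrow(elements) == 0) {
    abort("no elements survive the requested scope and suppression")
  }
  summary <- summarize_dictionary(elements, config)

  pairs <- build_element_value_table(value_events, concepts, elements, config)
  if (suppress) {
    pairs <- suppress_small_cells(pairs, config)
    suppression$pairs <- suppression_outcome(pairs)
  }
  values <- build_value_dictionary(pairs, concepts, config)
  avoidance <- detect_answer_avoidance(
    pairs, config,
    n_elements_total = nrow(elements)
  )
  value_profile <- value_terminology_profile(
    values, pairs, config,
    n_elements_total = nrow(elements)
  )
  concordance <- element_value_concordance(elements, pairs, config)

  crossover <- find_crossover_elements(
    attributed, config, concepts,
    total_participants = total_participants
  )
  if (suppress) {
    crossover <- suppress_small_cells(crossover, config)
    suppression$crossover <- suppression_outcome(crossover)
  }
  axes <- classify_axes(elements, crossover, healthcare_elements)

  structure(
    list(
      elements = elements, summary = summary, pairs = pairs,
      values = values, value_profile = value_profile,
      avoidance = avoidance, concordance = concordance,
      crossover = crossover, axes = axes,
      suppression = suppression, config = config,
      total_participants = total_participants %||%
        n_distinct(events$person_id)
    ),
    class = "omop_cde_profile"
  )
}

#' Profile a generated study bundle
#'
#' Convenience wrapper: unpacks the bundle produced by [generate_study()] or
#' [make_reference_study()] and calls [profile_study()].
#'
#' @param bundle A study bundle.
#' @param ... Passed on to [profile_study()].
#' @return An `omop_cde_profile`.
#' @export
profile_bundle <- function(bundle, ...) {
  args <- list(
    events = bundle$events, concepts = bundle$concepts,
    relationships = bundle$relationships,
    initiative_lookup = bundle$initiative_lookup
  )
  dots <- list(...)
  if (!is.null(bundle$total_participants) &&
    !"total_participants" %in% names(dots)) {
    args$total_participants <- bundle$total_participants
  }
  do.call(profile_study, c(args, dots))
}

#' @export
print.omop_cde_profile <- function(x, ...) {
  t <- x$summary$totals
  cat("<omop_cde_profile>\n")
  cat(sprintf(
    "  %d elements (%d CDE [%.1f%%], %d UDE [%.1f%%])\n",
    t$total_elements, t$cde_elements, t$pct_cde, t$ude_elements, t$pct_ude
  ))
  cat(sprintf(
    "  %d categorical / %d numeric; %d initiative CDEs\n",
    t$categorical_elements, t$numeric_elements, t$initiative_cdes
  ))
  cat(sprintf(
    "  %d distinct values over %d element-value combinations\n",
    nrow(x$values), nrow(x$pairs)
  ))
  cat(sprintf(
    "  avoidance: %d skip-enabled (%.1f%%), %d avoidance-enabled (%.1f%%)\n",
    x$avoidance$summary$skip_enabled, x$avoidance$summary$pct_skip_enabled,
    x$avoidance$summary$avoidance_enabled,
    x$avoidance$summary$pct_avoidance_enabled
  ))
  cat(sprintf("  %d CRF/EHR crossover elements\n", nrow(x$crossover)))
  invisible(x)
}

#' Tidy a study profile into one of its component tables
#'
#' @param x An `omop_cde_profile`.
#' @param table One of `"elements"`, `"pairs"`, `"values"`,
#'   `"value_profile"`, `"crossover"`, `"axes"`, `"concordance"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.omop_cde_profile <- function(x, table = "elements", ...) {
  table <- match.arg(
    table,
    c(
      "elements", "pairs", "values", "value_profile", "crossover",
      "axes", "concordance"
    )
  )
  switch(table,
    elements = x$elements,
    pairs = x$pairs,
    values = x$values,
    value_profile = x$value_profile,
    crossover = x$crossover,
    axes = x$axes,
    concordance = x$concordance$records
  )
}

#' One-row headline summary of a study profile
#'
#' @param x An `omop_cde_profile`.
#' @param ... Unused.
#' @return A one-row tibble with the audit's headline quantities.
#' @export
glance.omop_cde_profile <- function(x, ...) {
  t <- x$summary$totals
  vals <- x$values
  nd <- x$config$percent_decimals
  single_use <- sum(vals$n_elements == 1)
  standardized <- sum(vals$standardized)
  o1 <- x$axes$element_count[
    x$axes$origin == "O1-healthcare" & x$axes$ingestion == "T1-ingested"
  ]
  o2 <- x$axes$element_count[
    x$axes$origin == "O2-research" & x$axes$ingestion == "T1-ingested"
  ]
  tibble(
    total_elements = t$total_elements,
    cde_elements = t$cde_elements,
    ude_elements = t$ude_elements,
    pct_cde = t$pct_cde,
    pct_ude = t$pct_ude,
    numeric_elements = t$numeric_elements,
    categorical_elements = t$categorical_elements,
    initiative_cdes = t$initiative_cdes,
    distinct_values = nrow(vals),
    element_value_pairs = nrow(x$pairs),
    single_use_values = single_use,
    pct_single_use_values = pct_of(single_use, nrow(vals), nd),
    standardized_values = standardized,
    pct_standardized_values = pct_of(standardized, nrow(vals), nd),
    skip_enabled_elements = x$avoidance$summary$skip_enabled,
    pct_skip_enabled = x$avoidance$summary$pct_skip_enabled,
    avoidance_enabled_elements = x$avoidance$summary$avoidance_enabled,
    crossover_elements = nrow(x$crossover),
    healthcare_ingested_cdes = o1,
    research_ingested_cdes = o2,
    total_participants = x$total_participants
  )
}

#' Plot a study profile
#'
#' Quick ggplot2 views of a profile: the element census by vocabulary
#' (filled by CDE/UDE origin), the per-CRF element counts, or the
#' value-terminology profile.
#'
#' @param object An `omop_cde_profile`.
#' @param type `"vocabulary"`, `"crf"` or `"values"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omop_cde_profile <- function(object,
                                      type = c("vocabulary", "crf", "values"),
                                      ...) {
  type <- match.arg(type)
  if (type == "vocabulary") {
    dat <- count(
      object$elements, .data$vocabulary_id, .data$origin_class,
      name = "elements"
    )
    return(
      ggplot2::ggplot(dat, ggplot2::aes(
        x = stats::reorder(.data$vocabulary_id, -.data$elements),
        y = .data$elements, fill = .data$origin_class
      )) +
        ggplot2::geom_col() +
        ggplot2::labs(
          x = "Vocabulary", y = "Elements", fill = "Origin",
          title = "Data elements by terminology"
        ) +
        ggplot2::theme_minimal()
    )
  }
  if (type == "crf") {
    dat <- tidyr::pivot_longer(
      object$summary$by_crf, c("udes", "cdes"),
      names_to = "origin", values_to = "n"
    )
    return(
      ggplot2::ggplot(dat, ggplot2::aes(
        x = stats::reorder(.data$crf, .data$elements),
        y = .data$n, fill = .data$origin
      )) +
        ggplot2::geom_col() +
        ggplot2::coord_flip() +
        ggplot2::labs(
          x = NULL, y = "Elements", fill = NULL,
          title = "Elements per case report form"
        ) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$value_profile, ggplot2::aes(
    x = stats::reorder(.data$vocabulary_id, -.data$distinct_values),
    y = .data$distinct_values
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Value terminology", y = "Distinct values",
      title = "Permissible values by terminology"
    ) +
    ggplot2::theme_minimal()
}
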