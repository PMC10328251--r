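test_that("element dictionary counts events and participants per element", {
  concepts <- make_concepts(c(1, 2), vocab = c("LOINC", "PPI"))
  events <- make_events(
    element = c(1, 1, 1, 2),
    person = c(1, 2, 1, 1),
    value_concept = 0L
  )
  dict <- build_element_dictionary(events, concepts)
  expect_equal(dict$concept_id, c(1L, 2L))
  expect_equal(dict$event_count, c(3L, 1L))
  expect_equal(dict$participant_count, c(2L, 1L))
  # inferred denominator: 2 distinct persons in the store
  expect_equal(dict$participant_pct, c(100, 50))
  # a supplied denominator overrides the inferred one
  dict2 <- build_element_dictionary(
    events, concepts,
    total_participants = 10
  )
  expect_equal(dict2$participant_pct, c(20, 10))
  # empty store is an empty dictionary, not an error
  expect_equal(nrow(build_element_dictionary(events[0, ], concepts)), 0L)
})

test_that("large event volumes are counted exactly", {
  # volume of the most-used published element: 13 609 305 heart-rate rows
  n <- 13609305L
  events <- tibble::tibble(
    event_id = seq_len(n),
    person_id = (seq_len(n) - 1L) %% 270124L + 1L,
    element_concept_id = 3027018L,
    domain = "measurement",
    value_as_number = 72,
    value_as_concept_id = NA_integer_,
    src_id = "PPI/PM"
  )
  dict <- build_element_dictionary(
    events, make_concepts(3027018L, vocab = "LOINC")
  )
  expect_equal(dict$event_count, n)
  expect_equal(dict$participant_count, 270124L)
  expect_equal(dict$data_type, "numeric")
})

test_that("origin classification is by vocabulary membership", {
  cfg <- profile_config()
  expect_equal(classify_element_origin("LOINC", cfg), "CDE")
  expect_equal(classify_element_origin("PPI", cfg), "UDE")
  expect_equal(classify_element_origin("AoU_General", cfg), "UDE")
  expect_equal(
    classify_element_origin(c("SNOMED", "UCUM", "PPI"), cfg),
    c("CDE", "CDE", "UDE")
  )
  expect_error(classify_element_origin(""), "non-empty")
})

test_that("data-type rule is strict majority on value_as_number", {
  ev <- function(n_num, n_cat) {
    make_events(
      element = 1, person = seq_len(n_num + n_cat),
      value_num = c(rep(1, n_num), rep(NA, n_cat)),
      value_concept = c(rep(NA_integer_, n_num), rep(9L, n_cat))
    )
  }
  expect_equal(classify_data_type(ev(60, 40)), "numeric")
  # exactly half is NOT a majority: the inequality is strict
  expect_equal(classify_data_type(ev(50, 50)), "categorical")
  expect_equal(classify_data_type(ev(51, 49)), "numeric")
  expect_error(classify_data_type(ev(1, 1)[0, ]), "without data rows")

  # random mixtures agree with direct counting
  set.seed(42)
  for (i in 1:20) {
    n_num <- sample(0:30, 1)
    n_cat <- sample(1:30, 1)
    expected <- if (n_num / (n_num + n_cat) > 0.5) "numeric" else "categorical"
    expect_equal(classify_data_type(ev(n_num, n_cat)), expected)
  }
})

test_that("initiative mapping touches only LOINC CDEs", {
  elements <- tibble::tibble(
    concept_id = 1:3,
    vocabulary_id = c("LOINC", "LOINC", "PPI"),
    concept_code = c("63513-6", "61579-9", "63513-6"),
    origin_class = c("CDE", "CDE", "UDE")
  )
  lookup <- tibble::tibble(
    loinc_code = c("63513-6", "61579-9"),
    initiative = c("PhenX", "PROMIS")
  )
  out <- map_initiative(elements, lookup)
  expect_equal(out$initiative, c("PhenX", "PROMIS", NA))
  # no lookup, no initiative
  expect_true(all(is.na(map_initiative(elements, NULL)$initiative)))
})

test_that("CRF assignment walks the hierarchy to topic and module", {
  concepts <- dplyr::bind_rows(
    make_concepts(1, name = "How often do you have a drink containing alcohol"),
    make_concepts(2, name = "Alcohol", class = "Topic"),
    make_concepts(3, name = "Lifestyle", class = "Module"),
    make_concepts(4, name = "Orphan question")
  )
  edges <- tibble::tibble(
    subject_concept_id = c(1L, 2L),
    object_concept_id = c(2L, 3L),
    relationship_id = "Has parent"
  )
  out <- assign_crf(c(1L, 4L), edges, concepts)
  expect_equal(out$topic[out$element_concept_id == 1], "Alcohol")
  expect_equal(out$crf[out$element_concept_id == 1], "Lifestyle")
  # an element with no hierarchy edges gets the published fallback label
  expect_equal(out$crf[out$element_concept_id == 4], "No CRF Declared")

  # two modules at equal depth: lexicographically smaller wins, flagged
  concepts2 <- dplyr::bind_rows(
    concepts,
    make_concepts(5, name = "Basics", class = "Module")
  )
  edges2 <- dplyr::bind_rows(
    edges,
    tibble::tibble(
      subject_concept_id = 2L, object_concept_id = 5L,
      relationship_id = "Has parent"
    )
  )
  out2 <- assign_crf(1L, edges2, concepts2)
  expect_equal(out2$crf, "Basics")
  expect_true(out2$ambiguous)

  # cycles are an error naming the offending concepts
  cyc <- tibble::tibble(
    subject_concept_id = c(1L, 2L),
    object_concept_id = c(2L, 1L),
    relationship_id = "Has parent"
  )
  expect_error(assign_crf(1L, cyc, concepts), "cycle")

  # relationships outside the configured set are ignored
  other <- dplyr::mutate(edges, relationship_id = "Maps to")
  expect_equal(assign_crf(1L, other, concepts)$crf, "No CRF Declared")
})

test_that("dictionary summaries reproduce recounts and share arithmetic", {
  set.seed(7)
  study <- generate_study(generator_config(seed = 7, n_elements = 25))
  dict <- build_element_dictionary(
    study$events, study$concepts,
    relationships = study$relationships
  )
  oracle <- recount_elements(study$events)
  expect_equal(
    dict$event_count[order(dict$concept_id)],
    oracle$event_count
  )
  expect_equal(
    dict$participant_count[order(dict$concept_id)],
    oracle$participant_count
  )
  s <- summarize_dictionary(dict)
  expect_equal(sum(s$by_vocabulary$elements), s$totals$total_elements)
  expect_equal(sum(s$by_crf$elements), s$totals$total_elements)
  expect_equal(
    s$totals$cde_elements + s$totals$ude_elements, s$totals$total_elements
  )
  # single-element dictionary: its vocabulary holds 100% of elements
  one <- summarize_dictionary(dict[1, ])
  expect_equal(one$by_vocabulary$pct, 100)
  expect_error(summarize_dictionary(dict[0, ]), "empty")
})

test_that("published CDE share arithmetic: 164 of 1033 is 15.9%", {
  expect_equal(pct_of(164, 1033), 15.9)
  expect_equal(pct_of(103, 1033), 10.0)
  expect_equal(pct_of(869, 1033), 84.1)
  # round-half-up, not banker's rounding
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-2.25, 1), -2.3)
})

test_that("adding a new person never decreases participant coverage", {
  concepts <- make_concepts(1)
  events <- make_events(element = 1, person = c(1, 2, 3), value_concept = 9L)
  for (new_person in 4:8) {
    d0 <- build_element_dictionary(events, concepts, total_participants = 50)
    events <- dplyr::bind_rows(
      events,
      make_events(element = 1, person = new_person, value_concept = 9L)
    )
    d1 <- build_element_dictionary(events, concepts, total_participants = 50)
    expect_gte(d1$participant_count, d0$participant_count)
    expect_gte(d1$participant_pct, d0$participant_pct)
  }
})
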