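make_pair_fixture <- function() {
  # two categorical elements plus one numeric with stray coded rows
  concepts <- dplyr::bind_rows(
    make_concepts(1, vocab = "LOINC"),
    make_concepts(2, vocab = "PPI"),
    make_concepts(3, vocab = "LOINC"),
    make_concepts(c(10, 11), vocab = "LOINC", class = "Answer",
                  name = c("Yes", "No")),
    make_concepts(903096, vocab = "PPI", class = "Answer", name = "PMI: Skip")
  )
  events <- dplyr::bind_rows(
    make_events(1, person = 1:4, value_concept = c(10L, 10L, 10L, 11L)),
    make_events(2, person = 1:4, value_concept = c(10L, 903096L, NA, NA)),
    make_events(3, person = 1:2, value_num = 5, value_concept = c(10L, NA))
  )
  events$event_id <- seq_len(nrow(events))
  dict <- build_element_dictionary(events, concepts)
  list(concepts = concepts, events = events, dict = dict)
}

test_that("element-value pairs count and percentage per categorical element", {
  f <- make_pair_fixture()
  pairs <- build_element_value_table(f$events, f$concepts, f$dict)
  # element 1: Yes x3 (75%), No x1 (25%)
  e1 <- pairs[pairs$element_concept_id == 1, ]
  expect_equal(e1$count, c(3L, 1L))
  expect_equal(e1$pct_of_element, c(75, 25))
  # element 2 NONE rows are a sentinel pair with vocabulary "None"
  e2 <- pairs[pairs$element_concept_id == 2, ]
  expect_equal(e2$value_vocabulary[is.na(e2$value_concept_id)], "None")
  expect_equal(e2$count[is.na(e2$value_concept_id)], 2L)
  # the numeric element contributes no pairs but its coded rows are itemized
  expect_false(3 %in% pairs$element_concept_id)
  diag <- attr(pairs, "numeric_coded")
  expect_equal(diag$element_concept_id, 3L)
  expect_equal(diag$count, 1L)
})

test_that("published alcohol-frequency shares emerge from exact counts", {
  counts <- c(117229L, 81020L, 78459L, 58297L, 57085L, 9940L)
  expect_equal(sum(counts), 402030L) # the published element total
  concepts <- dplyr::bind_rows(
    make_concepts(40771103, vocab = "LOINC"),
    make_concepts(101:105, vocab = "LOINC", class = "Answer"),
    make_concepts(1177221, vocab = "LOINC", class = "Answer",
                  name = "I prefer not to answer")
  )
  events <- tibble::tibble(
    event_id = seq_len(sum(counts)),
    person_id = seq_len(sum(counts)),
    element_concept_id = 40771103L,
    domain = "observation",
    value_as_number = NA_real_,
    value_as_concept_id = rep(c(101:105, 1177221L), counts),
    src_id = "PPI/PM"
  )
  dict <- build_element_dictionary(events, concepts)
  pairs <- build_element_value_table(events, concepts, dict)
  expect_equal(pairs$pct_of_element[pairs$value_concept_id == 101], 29.2)
  expect_equal(pairs$pct_of_element[pairs$value_concept_id == 102], 20.2)
  expect_equal(sum(pairs$count), 402030L)
})

test_that("value dictionary aggregates across elements with conservation", {
  f <- make_pair_fixture()
  pairs <- build_element_value_table(f$events, f$concepts, f$dict)
  values <- build_value_dictionary(pairs, f$concepts)
  # value 10 is used by elements 1 and 2
  expect_equal(values$n_elements[values$value_concept_id %in% 10], 2L)
  # conservation: total usage equals total pair counts
  expect_equal(sum(values$total_count), sum(pairs$count))
  # custom-vocabulary values are not standardized; LOINC ones are
  expect_false(values$standardized[values$value_concept_id %in% 903096])
  expect_true(values$standardized[values$value_concept_id %in% 10])
})

test_that("answer avoidance flags skip and prefer-not-to-answer offers", {
  f <- make_pair_fixture()
  pairs <- build_element_value_table(f$events, f$concepts, f$dict)
  av <- detect_answer_avoidance(pairs)
  flags <- av$elements
  expect_false(flags$skip_enabled[flags$element_concept_id == 1])
  expect_true(flags$skip_enabled[flags$element_concept_id == 2])
  expect_equal(av$summary$skip_enabled, 1L)
  expect_equal(av$usage$total_count, 1L)
  # a supplied denominator expresses the share over all elements
  av2 <- detect_answer_avoidance(pairs, n_elements_total = 4)
  expect_equal(av2$summary$pct_skip_enabled, 25)
})

test_that("per-element value percentages sum to 100 within rounding", {
  set.seed(31)
  for (seed in c(2, 9, 17)) {
    study <- generate_study(generator_config(seed = seed, n_elements = 18))
    prof <- profile_bundle(study, suppress = FALSE)
    sums <- tapply(
      prof$pairs$pct_of_element, prof$pairs$element_concept_id, sum
    )
    n_vals <- tapply(prof$pairs$pct_of_element, prof$pairs$element_concept_id, length)
    expect_true(all(abs(sums - 100) <= 0.1 * n_vals))
  }
})

test_that("terminology profile counts elements once per value vocabulary", {
  f <- make_pair_fixture()
  pairs <- build_element_value_table(f$events, f$concepts, f$dict)
  values <- build_value_dictionary(pairs, f$concepts)
  prof <- value_terminology_profile(values, pairs)
  loinc <- prof[prof$vocabulary_id == "LOINC", ]
  expect_equal(loinc$distinct_values, 2L)
  expect_equal(loinc$elements, 2L) # elements 1 and 2 both use LOINC values
  expect_equal(prof$elements[prof$vocabulary_id == "PPI"], 1L)
  expect_equal(prof$elements[prof$vocabulary_id == "None"], 1L)
  expect_equal(sum(prof$distinct_values), nrow(values))
})

test_that("concordance classes partition categorical elements", {
  concepts <- dplyr::bind_rows(
    make_concepts(1, vocab = "PPI"), # UDE, all-LOINC values
    make_concepts(2, vocab = "PPI"), # UDE, all-PPI values
    make_concepts(3, vocab = "LOINC"), # CDE, LOINC + PPI values
    make_concepts(4, vocab = "LOINC"), # CDE, own-terminology value only
    make_concepts(c(10, 11), vocab = "LOINC", class = "Answer"),
    make_concepts(c(20, 21), vocab = "PPI", class = "Answer")
  )
  events <- dplyr::bind_rows(
    make_events(1, person = 1:2, value_concept = c(10L, 11L)),
    make_events(2, person = 1:2, value_concept = c(20L, 21L)),
    make_events(3, person = 1:2, value_concept = c(10L, 20L)),
    make_events(4, person = 1:2, value_concept = 10L)
  )
  events$event_id <- seq_len(nrow(events))
  dict <- build_element_dictionary(events, concepts)
  pairs <- build_element_value_table(events, concepts, dict)
  conc <- element_value_concordance(dict, pairs)
  cls <- setNames(conc$records$concordance_class, conc$records$element_concept_id)
  expect_equal(unname(cls["1"]), "different-terminology-only")
  expect_equal(unname(cls["2"]), "same-terminology-only")
  expect_equal(unname(cls["3"]), "mixed")
  expect_equal(unname(cls["4"]), "same-terminology-only")
  s <- conc$summary
  expect_equal(
    s$same_terminology_only + s$different_terminology_only + s$mixed,
    s$categorical_elements
  )
  # UDE/CDE cross-tabulations
  expect_equal(s$ude_only_standardized_values, 1L) # element 1
  expect_equal(s$ude_only_custom_values, 1L) # element 2
  expect_equal(s$cde_with_custom_values, 1L) # element 3
  expect_equal(s$ude_with_standardized_values, 1L)
})
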