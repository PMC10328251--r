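test_that("the reference study is deterministic and structurally sound", {
  s1 <- reference_study_cached()
  s2 <- make_reference_study()
  expect_identical(s1, s2)
  expect_equal(length(unique(s1$events$element_concept_id)), 1033L)
  expect_false(anyDuplicated(s1$concepts$concept_id) > 0)
  # every event resolves in the catalogue
  expect_true(all(s1$events$element_concept_id %in% s1$concepts$concept_id))
  expect_true(all(
    is.na(s1$events$value_as_concept_id) |
      s1$events$value_as_concept_id %in% s1$concepts$concept_id
  ))
})

test_that("profiling the reference study yields the published element census", {
  prof <- reference_profile()
  t <- prof$summary$totals
  expect_equal(t$total_elements, 1033L)
  expect_equal(t$cde_elements, 164L)
  expect_equal(t$ude_elements, 869L)
  expect_equal(t$pct_cde, 15.9)
  expect_equal(t$numeric_elements, 41L)
  expect_equal(t$categorical_elements, 992L)
  bv <- prof$summary$by_vocabulary
  expect_equal(bv$elements[bv$vocabulary_id == "LOINC"], 103L)
  expect_equal(bv$elements[bv$vocabulary_id == "SNOMED"], 60L)
  expect_equal(bv$elements[bv$vocabulary_id == "UCUM"], 1L)
  expect_equal(bv$elements[bv$vocabulary_id == "PPI"], 869L)
  expect_equal(bv$pct[bv$vocabulary_id == "LOINC"], 10.0)
})

test_that("initiative provenance matches the published initiative census", {
  prof <- reference_profile()
  t <- prof$summary$totals
  expect_equal(t$initiative_cdes, 87L)
  bi <- prof$summary$by_initiative
  expect_equal(bi$elements[bi$initiative == "PhenX"], 17L)
  expect_equal(bi$elements[bi$initiative == "PROMIS"], 15L)
  expect_equal(bi$pct_of_initiative_cdes[bi$initiative == "PhenX"], 19.54)
  expect_equal(dplyr::n_distinct(bi$initiative), 15L)
  # the flagship PhenX element carries its initiative
  expect_equal(
    prof$elements$initiative[prof$elements$concept_id == 40766240],
    "PhenX"
  )
})

test_that("the CRF census matches the published per-form counts", {
  prof <- reference_profile()
  bc <- prof$summary$by_crf
  expected <- c(
    "Personal Medical History" = 461L,
    "No CRF Declared" = 306L,
    "COVID-19 Participant Experience (COPE)" = 118L,
    "Healthcare Access & Utilization" = 57L,
    "GROR" = 26L,
    "The Basics" = 21L,
    "Lifestyle" = 14L,
    "Primary Consent Update" = 10L,
    "Overall Health" = 9L,
    "Family History" = 6L,
    "Consent PII" = 3L,
    "EHRConsent PII" = 2L
  )
  expect_equal(setNames(bc$elements, bc$crf), expected)
  expect_equal(bc$pct_of_total[bc$crf == "Personal Medical History"], 44.63)
  # only the three core CRFs contain CDEs
  expect_equal(bc$cdes[bc$crf == "The Basics"], 12L)
  expect_equal(bc$cdes[bc$crf == "Lifestyle"], 10L)
  expect_equal(bc$cdes[bc$crf == "Overall Health"], 1L)
  # the alcohol element resolves through its own topic
  expect_equal(
    prof$elements$topic[prof$elements$concept_id == 40771103], "Alcohol"
  )
  expect_equal(
    prof$elements$crf[prof$elements$concept_id == 40771103], "Lifestyle"
  )
})

test_that("the value catalogue matches the published value-level marginals", {
  prof <- reference_profile()
  g <- glance(prof)
  expect_equal(g$distinct_values, 932L)
  expect_equal(g$element_value_pairs, 4592L)
  expect_equal(g$single_use_values, 672L)
  expect_equal(g$pct_single_use_values, 72.1)
  expect_equal(g$standardized_values, 575L)
  expect_equal(g$pct_standardized_values, 61.7)
  vp <- prof$value_profile
  expect_equal(vp$distinct_values[vp$vocabulary_id == "SNOMED"], 357L)
  expect_equal(vp$distinct_values[vp$vocabulary_id == "LOINC"], 194L)
  expect_equal(vp$pct_of_values[vp$vocabulary_id == "LOINC"], 20.82)
  expect_equal(vp$elements[vp$vocabulary_id == "LOINC"], 748L)
  expect_equal(vp$pct_of_elements[vp$vocabulary_id == "LOINC"], 72.41)
  expect_equal(vp$elements[vp$vocabulary_id == "PPI"], 768L)
  expect_equal(vp$elements[vp$vocabulary_id == "None"], 68L)
})

test_that("avoidance and concordance marginals match the published audit", {
  prof <- reference_profile()
  av <- prof$avoidance$summary
  expect_equal(av$skip_enabled, 748L)
  expect_equal(av$pct_skip_enabled, 72.4)
  expect_equal(av$avoidance_enabled, 801L)
  pnta <- prof$avoidance$usage
  expect_equal(pnta$n_elements[pnta$value_concept_id == 1177221], 63L)
  cs <- prof$concordance$summary
  expect_equal(cs$same_terminology_only, 63L)
  expect_equal(cs$different_terminology_only, 186L)
  expect_equal(cs$ude_with_standardized_values, 819L)
  expect_equal(cs$ude_only_custom_values, 50L)
})

test_that("showcase elements carry their exact published value shares", {
  prof <- reference_profile()
  ins <- prof$pairs[prof$pairs$element_concept_id == 40766240, ]
  expect_equal(sum(ins$count), 931119L) # published element total
  expect_equal(ins$pct_of_element[ins$value_name == "Yes"], 59.5)
  expect_equal(ins$pct_of_element[ins$value_name == "PMI: Skip"], 1.0)
  # the SNOMED "No" among mostly PPI/LOINC values makes insurance mixed
  cls <- prof$concordance$records
  expect_equal(
    cls$concordance_class[cls$element_concept_id == 40766240], "mixed"
  )
  ho <- prof$pairs[prof$pairs$element_concept_id == 1585370, ]
  expect_equal(sum(ho$count), 329038L)
  expect_equal(max(ho$pct_of_element), 44.2)
})

test_that("crossover and axis classification match the published overlap", {
  prof <- reference_profile()
  expect_equal(nrow(prof$crossover), 64L)
  expect_true(all(prof$crossover$element_concept_id %in%
    prof$elements$concept_id[prof$elements$origin_class == "CDE"]))
  ax <- prof$axes
  expect_equal(
    ax$element_count[ax$origin == "O1-healthcare"], 64L
  )
  expect_equal(
    ax$element_count[
      ax$origin == "O2-research" & ax$ingestion == "T1-ingested"
    ],
    100L
  )
  expect_equal(
    ax$element_count[ax$ingestion == "T2-non-ingested"], 0L
  )
  expect_equal(attr(ax, "ude_count"), 869L)
  # heart rate is a crossover element dominated by EHR rows
  hr <- prof$crossover[prof$crossover$element_concept_id == 3027018, ]
  expect_equal(nrow(hr), 1L)
  expect_true(hr$ehr_event_count > 0 && hr$crf_event_count > 0)
})
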