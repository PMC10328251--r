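#' Synthetic reference study reproducing the published All of Us marginals
#'
#' Constructs, fully in code and with no randomness, an OMOP-shaped bundle
#' whose profile reproduces the headline marginals publicly reported for the
#' All of Us registered-tier R2021Q3R2 CRF data: 1 033 elements split
#' 103 LOINC / 60 SNOMED / 1 UCUM / 869 PPI (164 CDEs, 15.9%); 41 numeric
#' elements; 87 initiative CDEs (17 PhenX, 15 PROMIS, ...); the CRF census
#' (461 Personal Medical History, 306 No CRF Declared, ...); 932 distinct
#' permissible values (357 SNOMED, 194 LOINC, 575 standardized, 672
#' single-element) across 4 592 element-value combinations; 748
#' skip-enabled and 801 avoidance-enabled elements; and 64 CRF/EHR
#' crossover CDEs. The health-insurance, alcohol-frequency and home-own
#' elements carry their exact published value counts, so their per-value
#' percentages (59.5%, 29.2%, 44.2%) emerge from the data.
#'
#' Everything is synthetic: identifiers outside a handful of well-known
#' concepts (heart rate 3027018, `PMI: Skip` 903096, `I prefer not to
#' answer` 1177221, ...) are minted in disjoint synthetic ranges, and
#' person-level rows are allocated deterministically, not sampled. The
#' bundle is byte-identical across calls.
#'
#' @return A list: `concepts`, `relationships`, `events`,
#'   `initiative_lookup`, `total_participants` (329 070, the published
#'   participant denominator).
#' @export
#' @examples
#' \donttest{
#' study <- make_reference_study()
#' nrow(dplyr::distinct(study$events, element_concept_id)) # 1033
#' }
make_reference_study <- function() {
  skip_id <- 903096L
  pnta_id <- 1177221L

  # ---- shared value pools (multi-element values) -------------------------
  l_shared <- 2000001:2000059 # Yes, No, Don't know + 56 generic LOINC
  yes_id <- 2000001L
  dk_id <- 2000003L
  p_shared <- 2100001:2100099 # + PMI: Skip makes 100 distinct PPI values
  s_shared <- 2200001:2200096 # first is the SNOMED "No"
  no_snomed <- 2200001L
  a_shared <- 2300001:2300002
  u_shared <- 2400001L

  # ---- single-element value pools (each used exactly once) ---------------
  singles <- list(
    LOINC = 3000001:3000134, PPI = 3100001:3100244,
    SNOMED = 3200001:3200261, AoU_General = 3300001:3300011,
    ICD10CM = 3400001:3400009, ICD9CM = 3500001:3500011,
    UCUM = 3600001:3600002
  )
  cur <- new.env(parent = emptyenv())
  for (v in names(singles)) assign(paste0("single_", v), 0L, envir = cur)
  for (v in c("L", "P", "S", "A")) assign(paste0("shared_", v), 0L, envir = cur)
  take_shared <- function(pool, key, k) {
    i <- get(key, envir = cur)
    out <- pool[(i + seq_len(k) - 1L) %% length(pool) + 1L]
    assign(key, i + k, envir = cur)
    out
  }
  take_L <- function(k) take_shared(l_shared, "shared_L", k)
  take_P <- function(k) take_shared(p_shared, "shared_P", k)
  take_S <- function(k) take_shared(s_shared, "shared_S", k)
  take_A <- function(k) take_shared(a_shared, "shared_A", k)
  take_single <- function(vocab, k) {
    key <- paste0("single_", vocab)
    i <- get(key, envir = cur)
    stopifnot(i + k <= length(singles[[vocab]]))
    out <- singles[[vocab]][i + seq_len(k)]
    assign(key, i + k, envir = cur)
    out
  }

  # ---- element plan ------------------------------------------------------
  # Each group fixes vocabulary, value-vocabulary set, skip / prefer-not-to-
  # answer availability, and size; together they realise the published
  # terminology, avoidance and concordance marginals exactly.
  groups <- tibble(
    group = c(
      "U1a", "U1b", "U2", "U3", "U4", "U5a", "U5b", "U6", "U7",
      "U8", "U9", "U10", "U11", "U12",
      "L1a", "L1b", "L2a", "L2b", "L2c", "L3", "L4a", "L4b",
      "S2a", "S2b", "S3"
    ),
    n = c(
      19L, 19L, 10L, 2L, 90L, 51L, 39L, 17L, 451L,
      38L, 129L, 1L, 1L, 2L,
      1L, 24L, 1L, 9L, 20L, 2L, 1L, 5L,
      1L, 57L, 2L
    ),
    vocab = c(
      rep("PPI", 14),
      rep("LOINC", 8),
      rep("SNOMED", 3)
    )
  )
  el <- groups |>
    tidyr::uncount(.data$n, .id = "member") |>
    mutate(idx = row_number())
  n_categorical <- nrow(el) # 992

  # named elements reuse their well-known concept ids
  special_id <- c(
    U7_1 = 1585370L, # Home Own: Current Home Own (PPI)
    L1a_1 = 40771103L, # How often do you have a drink containing alcohol
    L2a_1 = 3046344L, # Marital status
    L4a_1 = 40766240L, # Health insurance coverage [PhenX]
    S2a_1 = 4214956L # History of clinical finding in subject
  )
  el <- el |>
    mutate(
      key = paste0(.data$group, "_", .data$member),
      concept_id = if_else(
        .data$key %in% names(special_id),
        unname(special_id[.data$key]), 1000000L + .data$idx
      ),
      is_homeown = .data$key == "U7_1",
      skip = .data$group %in% c(
        "U1a", "U2", "U7", "U8", "U9", "U10", "U11", "U12",
        "L2a", "L2b", "L2c", "L3", "L4a", "L4b", "S2a", "S2b", "S3"
      ) & !.data$is_homeown,
      pnta = .data$group %in% c("U5a", "L1a", "L2a", "L2b") | .data$is_homeown
    )

  # ---- per-element value picks -------------------------------------------
  # Value-set sizes are chosen so the combination total lands exactly on the
  # published 4 592 once the 564 remaining single-use values and the 68 NONE
  # combinations are added: U7 carries five values (skip + 2 LOINC + 2 PPI),
  # U4 four SNOMED-valued picks, U8 four, U6 three, and the first 13 L1b
  # elements three all-LOINC values.
  pick_values <- function(group, member, is_homeown) {
    if (is_homeown) {
      return(c(take_single("PPI", 3), pnta_id))
    }
    switch(group,
      U1a = c(skip_id, take_P(1)),
      U1b = take_P(2),
      U2 = c(skip_id, take_A(1)),
      U3 = take_A(1),
      U4 = take_S(4),
      U5a = c(pnta_id, take_L(1)),
      U5b = take_L(2),
      U6 = c(take_L(1), take_S(2)),
      U7 = c(skip_id, take_L(2), take_P(2)),
      U8 = c(skip_id, take_S(3)),
      U9 = c(skip_id, take_L(1), take_S(1)),
      U10 = c(skip_id, take_single("ICD10CM", 9)),
      U11 = c(skip_id, take_single("ICD9CM", 11)),
      U12 = c(skip_id, u_shared, take_single("UCUM", 1)),
      L1a = c(pnta_id, take_single("LOINC", 5)),
      L1b = take_L(if (member <= 13) 3 else 2),
      L2a = c(skip_id, pnta_id, take_single("LOINC", 6)),
      L2b = c(skip_id, pnta_id, take_L(2)),
      L2c = c(skip_id, take_L(2)),
      L3 = c(skip_id, take_P(1)),
      L4a = c(yes_id, dk_id, no_snomed, skip_id, take_single("PPI", 6)),
      L4b = c(skip_id, take_L(1), take_P(1), take_S(1)),
      S2a = c(skip_id, take_S(3), take_single("SNOMED", 55)),
      S2b = c(skip_id, take_S(2)),
      S3 = c(skip_id, take_P(1))
    )
  }
  value_sets <- purrr::pmap(
    list(el$group, el$member, el$is_homeown), pick_values
  )

  # U3's two elements additionally carry their private AoU_General values
  u3_rows <- which(el$group == "U3")
  value_sets[[u3_rows[1]]] <- c(value_sets[[u3_rows[1]]], take_single("AoU_General", 5))
  value_sets[[u3_rows[2]]] <- c(value_sets[[u3_rows[2]]], take_single("AoU_General", 6))

  # ---- distribute the remaining single-use values ------------------------
  give_singles <- function(rows, vocab) {
    left <- length(singles[[vocab]]) - get(paste0("single_", vocab), envir = cur)
    for (r in rows[seq_len(left)]) {
      value_sets[[r]] <<- c(value_sets[[r]], take_single(vocab, 1L))
    }
  }
  u9_rows <- which(el$group == "U9")
  give_singles(u9_rows, "LOINC")
  give_singles(which(el$group == "U7" & !el$is_homeown), "PPI")
  give_singles(
    c(
      which(el$group == "U4"), which(el$group == "S2b"),
      which(el$group == "U8"), which(el$group == "U6"), u9_rows
    ),
    "SNOMED"
  )
  for (v in names(singles)) {
    stopifnot(get(paste0("single_", v), envir = cur) == length(singles[[v]]))
  }

  # ---- pair counts -------------------------------------------------------
  # default 20 rows (20 distinct participants) per combination; the three
  # showcase elements carry their exact published value counts
  exact_counts <- list(
    L4a_1 = c(554459L, 3270L, 27820L, 9429L, 136606L, 110455L, 42737L,
              21589L, 12501L, 11955L),
    L1a_1 = c(9940L, 117229L, 81020L, 78459L, 58297L, 57085L),
    U7_1 = c(145365L, 133659L, 35481L, 14419L)
  )
  pair_counts <- purrr::map2(el$key, value_sets, function(key, vals) {
    if (key %in% names(exact_counts)) {
      exact_counts[[key]]
    } else {
      rep(20L, length(vals))
    }
  })

  # rows with no coded value: published top-ups for insurance (298) and
  # home own (114) plus 66 further elements, giving 68 "None" elements
  none_rows <- integer(nrow(el))
  none_rows[el$key == "L4a_1"] <- 298L
  none_rows[el$key == "U7_1"] <- 114L
  plain_u7 <- which(el$group == "U7" & !el$is_homeown)
  none_rows[plain_u7[seq_len(66L)]] <- 20L

  # ---- numeric elements --------------------------------------------------
  numeric_el <- tibble(
    concept_id = c(3027018L, 3025315L, 1000000L + n_categorical + 1:38, 8621L),
    concept_name = c(
      "Heart rate", "Body weight",
      sprintf("Synthetic quantitative measurement %02d", 1:38),
      "Days per week?"
    ),
    vocabulary_id = c(rep("LOINC", 40), "UCUM"),
    concept_code = c(
      "8867-4", "29463-7", sprintf("9%03d-%d", 1:38, (1:38) %% 9),
      "d/wk"
    )
  )

  # ---- CRF hierarchy -----------------------------------------------------
  modules <- tibble(
    concept_id = 4100001:4100011,
    concept_name = c(
      "Personal Medical History",
      "COVID-19 Participant Experience (COPE)",
      "Healthcare Access & Utilization", "GROR", "The Basics", "Lifestyle",
      "Primary Consent Update", "Overall Health", "Family History",
      "Consent PII", "EHRConsent PII"
    )
  )
  topics <- tibble(
    concept_id = 4000001:4000012,
    concept_name = c(
      sprintf("%s topic", modules$concept_name), "Alcohol"
    ),
    module_id = c(modules$concept_id, 4100006L) # Alcohol sits in Lifestyle
  )
  module_of_topic <- stats::setNames(topics$module_id, topics$concept_id)
  topic_named <- stats::setNames(topics$concept_id, topics$concept_name)

  crf_assign <- integer(0) # element concept_id -> topic concept_id
  assign_topic <- function(ids, module_name) {
    topic <- topic_named[[paste0(module_name, " topic")]]
    stats::setNames(rep(topic, length(ids)), ids)
  }
  ude_ids <- function(group) el$concept_id[el$group == group & !el$is_homeown]
  u7_ids <- ude_ids("U7")
  u4_ids <- ude_ids("U4")
  u8_ids <- ude_ids("U8")
  u9_ids <- ude_ids("U9")
  l2c_ids <- ude_ids("L2c")
  crf_assign <- c(
    assign_topic(c(u7_ids[1:450], u4_ids[1:11]), "Personal Medical History"),
    assign_topic(
      c(u4_ids[12:90], u8_ids, u9_ids[1]),
      "COVID-19 Participant Experience (COPE)"
    ),
    assign_topic(u9_ids[2:58], "Healthcare Access & Utilization"),
    assign_topic(u9_ids[59:84], "GROR"),
    assign_topic(u9_ids[85:94], "Primary Consent Update"),
    assign_topic(u9_ids[95:100], "Family History"),
    assign_topic(u9_ids[101:103], "Consent PII"),
    assign_topic(u9_ids[104:105], "EHRConsent PII"),
    # The Basics: insurance + marital + 10 LOINC CDEs + home own + 8 UDEs
    assign_topic(
      c(40766240L, 3046344L, l2c_ids[1:10], 1585370L, u9_ids[106:113]),
      "The Basics"
    ),
    # Overall Health: one CDE + 8 UDEs
    assign_topic(c(l2c_ids[11], u9_ids[114:121]), "Overall Health"),
    # Lifestyle: 9 CDEs + 4 UDEs via the module topic ...
    assign_topic(c(ude_ids("L2b"), u9_ids[122:125]), "Lifestyle"),
    # ... and the alcohol element through its own Alcohol topic
    stats::setNames(topic_named[["Alcohol"]], 40771103L)
  )

  # ---- initiative lookup -------------------------------------------------
  loinc_cat <- filter(el, .data$vocab == "LOINC")
  loinc_codes <- c(
    stats::setNames("63513-6", 40766240L),
    stats::setNames("68518-0", 40771103L),
    stats::setNames("45404-1", 3046344L),
    stats::setNames(
      sprintf("6%04d-%d", loinc_cat$idx, loinc_cat$idx %% 9),
      loinc_cat$concept_id
    )[!loinc_cat$concept_id %in% c(40766240L, 40771103L, 3046344L)],
    stats::setNames(numeric_el$concept_code[1:40], numeric_el$concept_id[1:40])
  )
  initiative_names <- c(
    rep("PhenX", 17), rep("PROMIS", 15), rep("Reported.PHQ", 14),
    rep("Perceived Stress Scale-10", 10), rep("MOS Social Support Survey", 9),
    rep("HHS.ACA Section 4302", 6), rep("SAMHSA", 5), rep("IPAQ", 3),
    rep("UCLA Loneliness Scale v3", 2),
    "AUDADIS-IV", "PATH", "BRFSS", "NHIS", "AUDIT-C", "NHANES"
  )
  init_elements <- c(
    40766240L, # insurance is the flagship PhenX CDE
    setdiff(as.integer(names(loinc_codes)), 40766240L)[1:86]
  )
  initiative_lookup <- tibble(
    loinc_code = unname(loinc_codes[as.character(init_elements)]),
    initiative = initiative_names
  )

  # ---- expand events -----------------------------------------------------
  person_pool <- 329070L
  crossover_ids <- c(
    numeric_el$concept_id, # all 41 numeric elements
    40771103L, 4214956L, # alcohol + history of clinical finding
    el$concept_id[el$group == "L1b"][1:21]
  )
  cat_plan <- tibble(
    element_concept_id = rep(el$concept_id, lengths(value_sets)),
    value_concept_id = unlist(value_sets),
    count = unlist(pair_counts)
  )
  none_plan <- tibble(
    element_concept_id = el$concept_id[none_rows > 0],
    value_concept_id = NA_integer_,
    count = none_rows[none_rows > 0]
  )
  plan <- bind_rows(cat_plan, none_plan) |>
    arrange(.data$element_concept_id)
  ev_element <- rep(plan$element_concept_id, plan$count)
  ev_value <- rep(plan$value_concept_id, plan$count)
  # plan rows are contiguous per element, so within-element row numbers come
  # from run lengths; persons cycle 1..329070 within each element
  row_in_element <- sequence(rle(ev_element)$lengths)
  ev_person <- (row_in_element - 1L) %% person_pool + 1L
  cat_events <- tibble(
    person_id = ev_person,
    element_concept_id = ev_element,
    value_as_number = NA_real_,
    value_as_concept_id = ev_value,
    src_id = "PPI/PM"
  )
  num_events <- tibble(
    person_id = rep(1:40, times = nrow(numeric_el)),
    element_concept_id = rep(numeric_el$concept_id, each = 40L),
    value_as_number = rep(60 + (1:40) * 1.5, times = nrow(numeric_el)),
    value_as_concept_id = NA_integer_,
    src_id = "PPI/PM"
  )
  ehr_events <- tibble(
    person_id = rep(1:20, times = length(crossover_ids)),
    element_concept_id = rep(crossover_ids, each = 20L),
    value_as_number = if_else(
      rep(crossover_ids %in% numeric_el$concept_id, each = 20L),
      rep(80 + (1:20) * 2.0, times = length(crossover_ids)), NA_real_
    ),
    value_as_concept_id = NA_integer_,
    src_id = sprintf("site_%02d", rep_len(1:3, 20L * length(crossover_ids)))
  )
  events <- bind_rows(cat_events, num_events, ehr_events)
  events <- mutate(
    events,
    event_id = row_number(),
    domain = if_else(
      .data$element_concept_id %in%
        c(numeric_el$concept_id, el$concept_id[el$vocab != "PPI"]),
      "measurement", "observation"
    ),
    .before = 1
  ) |>
    select(
      "event_id", "person_id", "element_concept_id", "domain",
      "value_as_number", "value_as_concept_id", "src_id"
    )

  # ---- concept catalogue -------------------------------------------------
  named_values <- tibble(
    concept_id = c(skip_id, pnta_id, yes_id, 2000002L, dk_id, no_snomed),
    concept_name = c(
      "PMI: Skip", "I prefer not to answer", "Yes", "No", "Don't know", "No"
    ),
    vocabulary_id = c("PPI", "LOINC", "LOINC", "LOINC", "LOINC", "SNOMED"),
    concept_code = c(
      "PMI_Skip", "LA29631-1", "LA33-6", "LA32-8", "LA12688-0", "267064002"
    )
  )
  generic_value <- function(ids, vocab, label) {
    tibble(
      concept_id = as.integer(ids),
      concept_name = sprintf("%s value %07d", label, as.integer(ids)),
      vocabulary_id = vocab,
      concept_code = sprintf("%s-%07d", substr(vocab, 1, 2), as.integer(ids))
    )
  }
  value_concepts <- bind_rows(
    named_values,
    generic_value(setdiff(l_shared, c(yes_id, 2000002L, dk_id)), "LOINC", "Shared LOINC"),
    generic_value(p_shared, "PPI", "Shared PPI"),
    generic_value(setdiff(s_shared, no_snomed), "SNOMED", "Shared SNOMED"),
    generic_value(a_shared, "AoU_General", "Shared AoU"),
    generic_value(u_shared, "UCUM", "Shared UCUM"),
    generic_value(singles$LOINC, "LOINC", "Single LOINC"),
    generic_value(singles$PPI, "PPI", "Single PPI"),
    generic_value(singles$SNOMED, "SNOMED", "Single SNOMED"),
    generic_value(singles$AoU_General, "AoU_General", "Single AoU"),
    generic_value(singles$ICD10CM, "ICD10CM", "Single ICD10"),
    generic_value(singles$ICD9CM, "ICD9CM", "Single ICD9"),
    generic_value(singles$UCUM, "UCUM", "Single UCUM")
  ) |>
    mutate(concept_class = "Answer", is_standard = TRUE)

  special_names <- c(
    "1585370" = "Home Own: Current Home Own",
    "40771103" = "How often do you have a drink containing alcohol",
    "3046344" = "Marital status",
    "40766240" = paste(
      "Are you covered by health insurance or some other kind of health",
      "care plan [PhenX]"
    ),
    "4214956" = "History of clinical finding in subject"
  )
  element_concepts <- tibble(
    concept_id = el$concept_id,
    concept_name = if_else(
      as.character(el$concept_id) %in% names(special_names),
      unname(special_names[as.character(el$concept_id)]),
      sprintf("Synthetic survey element %04d", el$idx)
    ),
    vocabulary_id = el$vocab,
    concept_code = dplyr::coalesce(
      unname(loinc_codes[as.character(el$concept_id)]),
      sprintf("Q%07d", el$concept_id)
    ),
    concept_class = "Question",
    is_standard = TRUE
  )
  concepts <- bind_rows(
    element_concepts,
    mutate(
      numeric_el,
      concept_class = "Question", is_standard = TRUE
    ),
    value_concepts,
    tibble(
      concept_id = topics$concept_id, concept_name = topics$concept_name,
      vocabulary_id = "PPI", concept_code = "",
      concept_class = "Topic", is_standard = TRUE
    ),
    tibble(
      concept_id = modules$concept_id, concept_name = modules$concept_name,
      vocabulary_id = "PPI", concept_code = "",
      concept_class = "Module", is_standard = TRUE
    )
  )

  relationships <- bind_rows(
    tibble(
      subject_concept_id = as.integer(names(crf_assign)),
      object_concept_id = unname(crf_assign),
      relationship_id = "Has parent"
    ),
    tibble(
      subject_concept_id = topics$concept_id,
      object_concept_id = unname(module_of_topic[as.character(topics$concept_id)]),
      relationship_id = "Has parent"
    )
  )

  stopifnot(
    nrow(el) + nrow(numeric_el) == 1033L,
    nrow(plan) == 4592L,
    !anyDuplicated(plan[c("element_concept_id", "value_concept_id")]),
    sum(el$skip) == 748L,
    sum(el$skip | el$pnta) == 801L,
    length(crossover_ids) == 64L
  )
  list(
    concepts = validate_concepts(concepts),
    relationships = relationships,
    events = events,
    initiative_lookup = initiative_lookup,
    total_participants = person_pool
  )
}
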