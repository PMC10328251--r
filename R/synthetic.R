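#' Configuration for the synthetic OMOP study generator
#'
#' Describes a planted study: how many participants and elements, the
#' vocabulary mixture (which drives the CDE/UDE split), the numeric share,
#' value-set sizes, skip availability and use, CRF/EHR crossover, and the
#' CRF hierarchy layout. Category *counts* are derived from the proportions
#' by exact largest-remainder allocation, so the generator's ground truth is
#' exact rather than statistical; the seed only permutes identifiers and
#' assignments.
#'
#' @param seed Integer RNG seed.
#' @param n_participants Number of participants in the person pool.
#' @param n_elements Number of data elements.
#' @param vocabulary_mixture Named proportions over vocabularies (must sum
#'   to 1); names outside `custom_vocabularies` of the profiling config
#'   yield CDEs.
#' @param numeric_fraction Proportion of elements that are numeric.
#' @param values_min,values_max Range of substantive values per categorical
#'   element (>= 1).
#' @param skip_enabled_fraction Proportion of categorical elements whose
#'   value set includes the skip concept.
#' @param avoidance_use_rate Per-element share of rows answered with the
#'   skip value when available.
#' @param crossover_fraction Proportion of elements that also receive EHR
#'   rows.
#' @param ehr_row_share Expected EHR share of a crossover element's rows.
#' @param initiative_fraction Proportion of LOINC elements assigned an
#'   initiative.
#' @param n_modules,topics_per_module CRF hierarchy layout.
#' @param no_crf_fraction Proportion of elements left out of the hierarchy
#'   (profiled as "No CRF Declared").
#' @param participants_min,participants_max Range of participants per
#'   element; the floor defaults to 20 so planted elements survive
#'   small-cell suppression.
#' @return A list with class `"omop_generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_participants = 200L,
                             n_elements = 40L,
                             vocabulary_mixture = c(
                               LOINC = 0.10, SNOMED = 0.06, UCUM = 0.0,
                               PPI = 0.80, AoU_General = 0.04
                             ),
                             numeric_fraction = 0.05,
                             values_min = 2L,
                             values_max = 6L,
                             skip_enabled_fraction = 0.7,
                             avoidance_use_rate = 0.05,
                             crossover_fraction = 0.1,
                             ehr_row_share = 0.3,
                             initiative_fraction = 0.5,
                             n_modules = 4L,
                             topics_per_module = 2L,
                             no_crf_fraction = 0.25,
                             participants_min = 20L,
                             participants_max = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    n_elements = as.integer(n_elements),
    vocabulary_mixture = vocabulary_mixture,
    numeric_fraction = numeric_fraction,
    values_min = as.integer(values_min),
    values_max = as.integer(values_max),
    skip_enabled_fraction = skip_enabled_fraction,
    avoidance_use_rate = avoidance_use_rate,
    crossover_fraction = crossover_fraction,
    ehr_row_share = ehr_row_share,
    initiative_fraction = initiative_fraction,
    n_modules = as.integer(n_modules),
    topics_per_module = as.integer(topics_per_module),
    no_crf_fraction = no_crf_fraction,
    participants_min = as.integer(participants_min),
    participants_max = as.integer(participants_max %||% n_participants)
  )
  props <- c(
    cfg$numeric_fraction, cfg$skip_enabled_fraction, cfg$avoidance_use_rate,
    cfg$crossover_fraction, cfg$ehr_row_share, cfg$initiative_fraction,
    cfg$no_crf_fraction
  )
  if (any(props < 0 | props > 1)) {
    abort("all proportions must lie in [0, 1]")
  }
  if (abs(sum(cfg$vocabulary_mixture) - 1) > 1e-9) {
    abort("vocabulary_mixture must sum to 1")
  }
  if (is.null(names(cfg$vocabulary_mixture)) ||
    any(names(cfg$vocabulary_mixture) == "")) {
    abort("vocabulary_mixture must be fully named")
  }
  if (cfg$values_min < 1L || cfg$values_max < cfg$values_min) {
    abort(
      "infeasible value-set sizes: a categorical element needs >= 1 value"
    )
  }
  if (cfg$participants_min < 1L ||
    cfg$participants_max > cfg$n_participants ||
    cfg$participants_min > cfg$participants_max) {
    abort("participants per element must fit inside the person pool")
  }
  if (cfg$n_elements < 1L || cfg$n_modules < 1L || cfg$topics_per_module < 1L) {
    abort("n_elements, n_modules and topics_per_module must be >= 1")
  }
  structure(cfg, class = "omop_generator_config")
}

# sample() treats a length-1 numeric x as 1:x; this does not.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Exact integer allocation of n units over proportions (largest remainder,
# ties broken by position). Guarantees sum(out) == n.
largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic OMOP study with planted ground truth
#'
#' Emits an OMOP-shaped bundle (CONCEPT, CONCEPT_RELATIONSHIP, clinical
#' events with per-row `src_id`, an initiative lookup) together with a
#' ground-truth manifest recording, per element, its vocabulary, origin
#' class, data type, CRF, initiative, skip availability, planted event /
#' participant counts, source split and value counts — everything the
#' profiling pipeline is expected to recover exactly. The same seed and
#' configuration reproduce the bundle bit for bit; changing only the seed
#' permutes identifiers and assignments but leaves every category count
#' unchanged.
#'
#' @param config A [generator_config()].
#' @param profile_cfg Profiling configuration (supplies the skip concept id
#'   and CRF source labels the bundle should use).
#' @return A list: `concepts`, `relationships`, `events`,
#'   `initiative_lookup`, `truth` (list with `elements` tibble and `globals`
#'   list).
#' @export
generate_study <- function(config = generator_config(),
                           profile_cfg = profile_config()) {
  stopifnot(inherits(config, "omop_generator_config"))
  profile_cfg <- as_profile_config(profile_cfg)
  set.seed(config$seed)
  n <- config$n_elements

  vocab_counts <- largest_remainder(config$vocabulary_mixture, n)
  vocabs <- rep(names(config$vocabulary_mixture), vocab_counts)
  vocabs <- sample(vocabs) # permute assignment, counts untouched

  n_numeric <- largest_remainder(
    c(config$numeric_fraction, 1 - config$numeric_fraction), n
  )[1]
  data_type <- sample(rep(
    c("numeric", "categorical"), c(n_numeric, n - n_numeric)
  ))

  n_categorical <- sum(data_type == "categorical")
  n_skip <- largest_remainder(
    c(config$skip_enabled_fraction, 1 - config$skip_enabled_fraction),
    n_categorical
  )[1]
  skip_enabled <- rep(FALSE, n)
  cat_idx <- which(data_type == "categorical")
  skip_enabled[resample(cat_idx, n_skip)] <- TRUE

  n_cross <- largest_remainder(
    c(config$crossover_fraction, 1 - config$crossover_fraction), n
  )[1]
  crossover <- rep(FALSE, n)
  crossover[sample.int(n, n_cross)] <- TRUE

  # identifiers: permuted by seed, disjoint ranges per role
  element_ids <- 1000L + sample.int(n) * 10L
  origin <- classify_element_origin(vocabs, profile_cfg)

  # initiative assignment over LOINC elements
  loinc_idx <- which(vocabs == "LOINC")
  n_init <- largest_remainder(
    c(config$initiative_fraction, 1 - config$initiative_fraction),
    length(loinc_idx)
  )[1]
  initiative <- rep(NA_character_, n)
  init_pool <- c("PhenX", "PROMIS", "Reported.PHQ", "SAMHSA", "IPAQ")
  if (n_init > 0) {
    chosen <- resample(loinc_idx, n_init)
    initiative[chosen] <- rep_len(init_pool, n_init)
  }
  concept_code <- sprintf("SYN%04d-%d", seq_len(n), config$seed %% 10L)

  # CRF hierarchy: modules > topics > elements; a planted share unassigned
  n_no_crf <- largest_remainder(
    c(config$no_crf_fraction, 1 - config$no_crf_fraction), n
  )[1]
  module_names <- sprintf("Module %02d", seq_len(config$n_modules))
  module_ids <- 900000L + seq_len(config$n_modules)
  n_topics <- config$n_modules * config$topics_per_module
  topic_ids <- 800000L + seq_len(n_topics)
  topic_module <- rep(seq_len(config$n_modules), each = config$topics_per_module)
  assigned <- rep(TRUE, n)
  if (n_no_crf > 0) {
    assigned[sample.int(n, n_no_crf)] <- FALSE
  }
  topic_of <- rep(NA_integer_, n)
  topic_of[assigned] <- rep_len(seq_len(n_topics), sum(assigned))
  crf <- if_else(
    assigned, module_names[topic_module[topic_of]], "No CRF Declared"
  )

  # per-element participants (contiguous person blocks keep counts exact)
  p_per_element <- resample(
    seq(config$participants_min, config$participants_max), n,
    replace = TRUE
  )
  block_start <- vapply(
    p_per_element,
    function(p) sample.int(config$n_participants - p + 1L, 1L),
    integer(1)
  )

  value_counter <- 0L
  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  value_concepts <- vector("list", n)
  value_vocab_pool <- c("LOINC", "SNOMED", "PPI")
  for (i in seq_len(n)) {
    p <- p_per_element[i]
    persons <- block_start[i] + seq_len(p) - 1L
    ehr_rows <- if (crossover[i]) {
      max(1L, min(p - 1L, as.integer(round(config$ehr_row_share * p))))
    } else {
      0L
    }
    crf_rows <- p - ehr_rows
    src <- c(
      rep(profile_cfg$crf_src_ids[1], crf_rows),
      rep(sprintf("site_%02d", rep_len(1:3, ehr_rows)), length.out = ehr_rows)
    )
    if (data_type[i] == "numeric") {
      value_num <- round(stats::rnorm(p, mean = 100, sd = 15), 1)
      value_id <- rep(NA_integer_, p)
      truth_values <- tibble(
        value_concept_id = integer(), count = integer()
      )
    } else {
      k <- resample(seq(config$values_min, config$values_max), 1L)
      ids <- 500000L + value_counter + seq_len(k)
      value_counter <- value_counter + k
      value_concepts[[i]] <- tibble(
        concept_id = ids,
        concept_name = sprintf("Value %d", ids),
        vocabulary_id = rep_len(value_vocab_pool, k),
        concept_code = sprintf("V%06d", ids),
        concept_class = "Answer",
        is_standard = TRUE
      )
      # at least one skip row when skip is offered, so the planted flag is
      # observable in data; never starve the substantive values entirely
      n_skip_rows <- if (skip_enabled[i]) {
        max(1L, as.integer(round(config$avoidance_use_rate * crf_rows)))
      } else {
        0L
      }
      n_skip_rows <- max(0L, min(n_skip_rows, crf_rows - k))
      substantive <- largest_remainder(rep(1 / k, k), crf_rows - n_skip_rows)
      value_set <- c(ids, if (skip_enabled[i]) profile_cfg$skip_concept_id)
      counts <- c(substantive, if (skip_enabled[i]) n_skip_rows)
      keep <- counts > 0
      truth_values <- tibble(
        value_concept_id = value_set[keep], count = counts[keep]
      )
      value_id <- c(
        rep(value_set, counts), # CRF rows carry the planted values
        rep(NA_integer_, ehr_rows) # EHR import arrives uncoded
      )
      value_num <- rep(NA_real_, p)
    }
    rows[[i]] <- tibble(
      person_id = persons,
      element_concept_id = element_ids[i],
      domain = if (vocabs[i] %in% profile_cfg$custom_vocabularies) {
        "observation"
      } else {
        "measurement"
      },
      value_as_number = value_num,
      value_as_concept_id = value_id,
      src_id = src
    )
    truth_rows[[i]] <- tibble(
      concept_id = element_ids[i],
      vocabulary_id = vocabs[i],
      origin_class = origin[i],
      data_type = data_type[i],
      crf = crf[i],
      initiative = initiative[i],
      skip_enabled = skip_enabled[i],
      crossover = crossover[i],
      event_count = p,
      participant_count = p,
      crf_event_count = crf_rows,
      ehr_event_count = ehr_rows,
      value_counts = list(truth_values)
    )
  }
  events <- bind_rows(rows)
  events <- mutate(events, event_id = row_number(), .before = 1)
  truth_elements <- bind_rows(truth_rows)

  # concept catalogue: elements + values + skip + topics + modules
  concepts <- bind_rows(
    tibble(
      concept_id = element_ids,
      concept_name = sprintf("Element %d", element_ids),
      vocabulary_id = vocabs,
      concept_code = concept_code,
      concept_class = "Question",
      is_standard = TRUE
    ),
    bind_rows(value_concepts),
    tibble(
      concept_id = profile_cfg$skip_concept_id,
      concept_name = "PMI: Skip",
      vocabulary_id = "PPI",
      concept_code = "PMI_Skip",
      concept_class = "Answer",
      is_standard = TRUE
    ),
    tibble(
      concept_id = topic_ids,
      concept_name = sprintf("Topic %02d", seq_len(n_topics)),
      vocabulary_id = "PPI",
      concept_code = "",
      concept_class = "Topic",
      is_standard = TRUE
    ),
    tibble(
      concept_id = module_ids,
      concept_name = module_names,
      vocabulary_id = "PPI",
      concept_code = "",
      concept_class = "Module",
      is_standard = TRUE
    )
  )
  relationships <- bind_rows(
    tibble(
      subject_concept_id = element_ids[assigned],
      object_concept_id = topic_ids[topic_of[assigned]],
      relationship_id = "Has parent"
    ),
    tibble(
      subject_concept_id = topic_ids,
      object_concept_id = module_ids[topic_module],
      relationship_id = "Has parent"
    )
  )
  lookup <- tibble(
    loinc_code = concept_code[!is.na(initiative)],
    initiative = initiative[!is.na(initiative)]
  )

  by_crf <- truth_elements |>
    count(.data$crf, name = "elements") |>
    arrange(desc(.data$elements), .data$crf)
  globals <- list(
    n_elements = n,
    cde_count = sum(origin == "CDE"),
    ude_count = sum(origin == "UDE"),
    numeric_count = sum(data_type == "numeric"),
    categorical_count = n_categorical,
    skip_enabled_count = n_skip,
    crossover_count = n_cross,
    by_crf = by_crf
  )
  list(
    concepts = validate_concepts(concepts),
    relationships = relationships,
    events = events,
    initiative_lookup = lookup,
    truth = list(elements = truth_elements, globals = globals)
  )
}
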