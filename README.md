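# omopcde

Audit the common-data-element content of OMOP-formatted study data.

Large cohort programs — All of Us being the motivating example — store both
research survey data (case report forms, CRFs) and imported electronic
health record (EHR) data in the OMOP Common Data Model. `omopcde` profiles
such a database on two levels:

* **data elements** — the `MEASUREMENT`/`OBSERVATION` concepts a study
  collects: usage volume, participant coverage, **CDE vs UDE** origin
  (a CDE lives in an established terminology such as LOINC or SNOMED CT; a
  UDE is minted in the study's custom vocabulary, e.g. `PPI`), the
  numeric/categorical data type (numeric iff > ½ of rows carry
  `value_as_number`), initiative provenance (PhenX, PROMIS, ... via LOINC
  method metadata) and CRF assignment through the `CONCEPT_RELATIONSHIP`
  hierarchy (element → topic → module);
* **permissible values** — element-value combinations and per-value usage,
  answer avoidance (`PMI: Skip`, `I prefer not to answer`),
  value-terminology profiles and element/value concordance;

plus CRF/EHR **crossover** (elements with rows from both sources and the
percent of events per source), a two-axis CDE classification
(origin × terminology ingestion), and **small-cell suppression**: no
exported aggregate row may represent fewer than 20 participants.

Because the real study data sit behind a restricted workbench, the package
ships two fully synthetic data sources: `generate_study()`, a seeded
generator with an exact planted ground-truth manifest, and
`make_reference_study()`, a deterministic bundle whose profile reproduces
the publicly reported All of Us registered-tier CRF marginals.

## Worked example

```r
library(omopcde)

study <- make_reference_study()        # deterministic synthetic bundle
prof  <- profile_bundle(study)         # full audit with suppression
prof
#> <omop_cde_profile>
#>   1033 elements (164 CDE [15.9%], 869 UDE [84.1%])
#>   992 categorical / 41 numeric; 87 initiative CDEs
#>   932 distinct values over 4592 element-value combinations
#>   avoidance: 748 skip-enabled (72.4%), 801 avoidance-enabled (77.5%)
#>   64 CRF/EHR crossover elements
```

Reading the numbers: of 1 033 CRF elements, only 15.9% could be expressed
in an established terminology (the CDEs); 72.4% of elements let the
participant skip the question; and 64 CDEs also occur in EHR-imported
data — these are the elements (vitals, alcohol use, smoking quantity)
whose answers routine care can refresh without repeating the survey.

The profile is a set of tibbles, so it pipes:

```r
library(dplyr)
glance(prof)                                   # one-row headline summary
tidy(prof, "elements") |> filter(origin_class == "CDE")
tidy(prof, "crossover") |> arrange(desc(event_count))
autoplot(prof, type = "crf")                   # per-CRF element census
```

On your own extracts:

```r
cfg      <- profile_config(min_participants = 20)
concepts <- read_concepts("CONCEPT.csv")
rel      <- read_relationships("CONCEPT_RELATIONSHIP.csv", concepts)
events   <- read_clinical_events(
  measurement_path = "MEASUREMENT.csv",
  observation_path = "OBSERVATION.csv",
  measurement_ext_path = "MEASUREMENT_EXT.csv",  # per-row src_id
  observation_ext_path = "OBSERVATION_EXT.csv",
  concepts = concepts, config = cfg
)
prof <- profile_study(events, concepts, relationships = rel,
                      initiative_lookup = read_initiative_lookup("initiatives.csv"),
                      config = cfg)
render_reports(prof, "report/")   # deterministic CSV bundle, suppressed
```

A thin CLI over the same functions lives at `inst/cli/omopcde.R`
(`profile`, `simulate`, `fixture` subcommands).

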