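Package: omopcde
Title: Common Data Element Audit for OMOP-Formatted Study Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-element and permissible-value dictionaries from OMOP
    Common Data Model study extracts, classifies elements as common data
    elements (CDEs) versus study-unique elements (UDEs), traces CDEs to data
    collection initiatives and case report forms via the concept-relationship
    hierarchy, quantifies answer avoidance and CRF/EHR crossover, and applies
    small-cell privacy suppression before export. Includes a deterministic
    synthetic OMOP study generator with a planted ground-truth manifest for
    end-to-end validation, plus a reference study encoding the publicly
    reported All of Us registered-tier CRF marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
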