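---
title: "Auditing common data elements in OMOP-formatted study data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing common data elements in OMOP-formatted study data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(omopcde)
library(dplyr)
```

## The problem

Large cohort programs such as All of Us collect survey (case report form,
CRF) data and import electronic health record (EHR) data into one OMOP
Common Data Model database. A recurring design question for such studies is
how much of their data dictionary is built from **common data elements**
(CDEs) — concepts drawn from established terminologies such as LOINC or
SNOMED CT, often originating in instruments like PhenX or PROMIS — versus
**unique data elements** (UDEs) minted in a study-specific vocabulary (All
of Us uses its `PPI` terminology, plus a small `AoU_General` set).

`omopcde` answers that question reproducibly. Given OMOP `CONCEPT`,
`CONCEPT_RELATIONSHIP`, `MEASUREMENT` and `OBSERVATION` extracts it builds:

* a **data-element dictionary**: per element, usage volume, participant
  coverage, CDE/UDE origin, numeric/categorical data type, initiative
  provenance and CRF assignment;
* a **permissible-value dictionary**: element-value combinations,
  per-value usage across elements, answer avoidance, and element/value
  terminology concordance;
* a **CRF/EHR crossover analysis**: which elements carry rows from both the
  research and the routine-healthcare source, and in what proportion;
* a **two-axis CDE classification** (origin x terminology ingestion); and
* **small-cell suppression** of every exportable aggregate.

## The classification rules

The audit's substance is a handful of deterministic rules; everything else
is counting.

**Origin.** An element is a UDE if and only if its `vocabulary_id` is in
the configured custom set (`PPI`, `AoU_General` by default); otherwise it
is a CDE. No semantic inspection is attempted — the vocabulary is the
authority.

**Data type.** An element is *numeric* when strictly more than half of its
data rows carry a `value_as_number`; otherwise it is *categorical*. The
strictness matters: an element with exactly half numeric rows is
categorical. The rule is row-weighted rather than per-site because element
use can vary across sites and the row census is what the model actually
stores.

**Initiative provenance.** LOINC ingests elements from prior data
collection instruments and records the instrument in its method metadata.
The audit reproduces that join as a lookup table from LOINC code to
initiative label; only LOINC CDEs can receive an initiative, and UDEs never
do. The lookup is an input file rather than bundled LOINC content, for
licensing reasons; the synthetic generator emits a matching lookup.

**CRF assignment.** OMOP's vocabulary layer expresses the survey structure
as concept relationships: question concepts point at topic concepts, topics
at module (CRF) concepts. The audit walks edges whose `relationship_id` is
in a configured list (default `Has parent`, `Is a`) upward from each
element, breadth-first, to a default depth of 5. The nearest concept whose
class is `Topic` is the element's topic; the nearest of class `Module` is
its CRF. Elements that reach no module are reported under
`"No CRF Declared"`, which in practice captures research-visit vitals such
as heart rate. The relationship types are configurable because the OMOP
vocabulary layer does not standardise which link carries the survey
hierarchy. Ties (two modules at the same depth) resolve to the
lexicographically smallest module name and are flagged in an `ambiguous`
column; cycles in the hierarchy are a hard error, since "upward" is
otherwise ill-defined.

**Source attribution.** Every row carries a `src_id`. Rows labelled
`PPI/PM` or `PM/PPI` (both spellings circulate) are CRF/research-visit
rows; anything else is an EHR site. The label may arrive in an extension
side table keyed on the event id, as an inline column, or not at all — the
physical transport is not standardised, so the reader accepts all three,
preferring the extension table. A crossover element is one with at least
one row from each source, with identity defined by exact concept id (no
semantic mapping across sites).

**Scope.** With the default `scope = "crf"`, the element universe is the
set of elements having at least one CRF row — the study's data-collection
catalogue. Usage counts still include EHR rows for those elements (this is
how an element like heart rate shows millions of events although nearly all
arrive by EHR import), while the value-level analysis uses CRF rows only.
`scope = "all"` profiles everything.

**Avoidance.** A categorical element is *skip-enabled* when its observed
value set contains the skip concept (903096, `PMI: Skip`), and
*avoidance-enabled* when it contains any configured avoidance concept
(903096 or 1177221, `I prefer not to answer`). Avoidance shares are
reported against the full element count, numeric elements included, since
the question "could the participant decline?" is asked of the element, not
of its rows.

**Concordance.** For each categorical element the set of terminologies
among its observed values (excluding the NONE sentinel, below) is compared
with the element's own: all values from one terminology equal to the
element's is *same-terminology-only*; all values from one terminology
different from the element's is *different-terminology-only*; two or more
value terminologies is *mixed*. The three classes partition the categorical
elements. An element whose only observed rows are uncoded falls in the
different-terminology class, as nothing it shows matches its own
vocabulary.

**The NONE sentinel.** OMOP rows may carry a `value_as_concept_id` of 0 or
nothing at all. Such rows are normalised to an explicit sentinel that
participates in the pair table and the value-terminology profile (as
vocabulary `"None"`) but never in avoidance or concordance. Keeping the
sentinel in the denominators is deliberate: a skip percentage is a share of
everything the element recorded, coded or not.

**Standardized values.** A distinct value is *standardized* when its
vocabulary is outside the custom set. The NONE sentinel's pseudo-vocabulary
`"None"` is not custom, so it counts as standardized — which is exactly how
the published standardized-value total (575 of 932) is reckoned; flipping
that convention would report 574.

**Suppression.** Any exportable table with a distinct-participant dimension
is filtered to rows representing at least `min_participants` (default 20)
participants; the threshold is inclusive, and the outcome (rows in / out /
suppressed) is attached to every filtered table. Suppression is applied per
row — for element-value tables this is per combination, the most
conservative reading. A table with no participant dimension (per-vocabulary
value counts, axis cells) is exempt but flagged in the report metadata. A
table that *should* have the column and does not is a hard error:
suppression must never silently pass.

## Numerical conventions

Percentages are rounded half away from zero (`round_half_up()`), not with
IEEE round-half-even, because that is how shares such as 164/1033 = 15.876
→ 15.9 are conventionally printed. Narrative percentages use 1 decimal,
tabular ones 2; both are configurable. Report files are written with a
fixed ordering — descending event count, ties by ascending concept id — so
that re-rendering identical inputs is byte-identical.

## The synthetic generator

`generate_study()` plants a study whose every profiled quantity is known in
advance, so the pipeline can be tested for *exact* recovery rather than
statistical agreement:

* Category counts (vocabulary mixture, numeric share, skip availability,
  crossover share, initiative share, CRF census) are fixed by
  largest-remainder allocation of the configured proportions. The seed
  permutes which element receives which category and all identifiers, but
  never the counts — two seeds differ in labels, not in marginals.
* Each element draws its participants as a contiguous person block, which
  keeps participant counts exact and controllable at the cost of realism.
* Per-element value counts are planted by exact allocation of the
  element's CRF rows over its value set, with at least one skip row when
  skip is offered (so the planted flag is always observable).
* Crossover elements receive a planted EHR row block; EHR rows of
  categorical elements arrive uncoded, mimicking sparse import.

What the generator does **not** emulate: realistic clinical value
distributions, longitudinal visits, inter-site heterogeneity, missingness
mechanisms, or semantic drift between sites' concept choices. A green
recovery suite therefore demonstrates that the audit counts, classifies and
attributes correctly on well-formed OMOP data — not that it is robust to
dirty real-world mappings, which the underlying model (trusting concept ids
as given) deliberately does not address.

`make_reference_study()` is the generator's deterministic sibling: a
hand-allocated bundle whose profile lands exactly on the publicly reported
All of Us registered-tier CRF marginals (1 033 elements, 164 CDEs, 932
values, 4 592 combinations, 748 skip-enabled, 64 crossover elements, the
per-CRF census, and the exact published value counts of the insurance,
alcohol-frequency and home-ownership showcase elements). Where the
published tables are mutually inconsistent — the per-CRF CDE/UDE columns
do not sum to the overall 164/869 split, and the concordance and
UDE-value counts imply numeric elements carried coded values — the
reference study keeps the totals that are consistent with the element
census (the per-form element counts, the three core forms' CDE counts, and
the 819/50 UDE value-usage split) and lets the remaining cells be what
arithmetic forces them to be. Participant-level volume is only realised
where the published numbers depend on it; every other combination carries
20 participants, the smallest exportable cell.

## Problem sizes used in the checks

The test suite profiles the reference study once (1 033 elements, about
1.8 million rows, a few seconds) and sweeps 50 generator configurations
spanning five vocabulary mixtures, three numeric fractions, two skip
fractions and three crossover fractions at 12–28 elements and 150
participants each — small enough to recover exactly and quickly, large
enough that every category is populated. One volume test counts a planted
13.6-million-row element to confirm that tallies do not degrade at
published scale.

## Known limitations

* CDE/UDE classification is purely vocabulary-based; an element minted in
  PPI that shadows an existing LOINC concept is still a UDE.
* Crossover detection requires exact concept agreement between CRF and EHR
  rows; sites mapping the same measurement to different concepts are
  invisible to it.
* The CRF dictionary is only as good as the relationship types configured;
  OMOP does not guarantee a unique upward path, and ambiguous assignments
  are flagged rather than resolved.
* Suppression implements the minimum-participant rule only — no rounding,
  no complementary suppression — matching the export policy it mirrors,
  not general statistical disclosure control.
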