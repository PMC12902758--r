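---
title: "Characterizing inpatient polypharmacy from OMOP-shaped records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing inpatient polypharmacy from OMOP-shaped records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrx)
library(data.table)
```

## The problem

Hospitalized older adults routinely receive many concurrent medications:
surgical admissions alone bring antibacterials, anesthetics, analgesics and
perioperative cardiac therapy together on the same days. The usual
outpatient definition of polypharmacy — five or more concurrent drugs — is
therefore a poor severity marker on inpatient data, where most patients
exceed it. `polyrx` implements a characterization pipeline for this
setting: it reconstructs continuous admission episodes from
OMOP-CDM-shaped visit records, counts the number of distinct drug
*ingredients* a patient is exposed to on each calendar day, summarizes each
patient by their maximum daily count, and assigns one of four severity
levels:

| maximum daily ingredient count | category |
|---|---|
| < 5 | nonpolypharmacy |
| 5–9 | polypharmacy |
| 10–19 | major polypharmacy |
| ≥ 20 | excessive polypharmacy |

On top of the per-patient assignment it mines prescribing patterns at the
WHO ATC second level (therapeutic subgroups such as J01, systemic
antibacterials): how many patients in each category used each subgroup at
least once, and which subgroup *combinations* were active on the
maximum-count day.

## Observation periods

The unit of observation is not the raw visit but the **continuous
admission episode**:

* only inpatient visits with an admission date inside the study window
  (default 2012-01-01 to 2020-12-31) enter;
* two consecutive admissions of the same patient merge when the next
  admission starts within 30 days of the previous discharge. We read
  "within 30 days" inclusively (a gap of exactly 30 days merges) and apply
  the rule transitively, so a chain of close admissions collapses into one
  episode spanning the earliest admission to the latest discharge.
  Overlapping or nested visit intervals always merge;
* each merged episode is followed for 7 calendar days after discharge, to
  capture discharge prescriptions filled in the outpatient setting. The
  discharge day itself belongs to the stay; the window is the 7 days after
  it. Because 30 > 7, a follow-up window can never reach the next episode
  of the same patient — a property the test suite checks on random cohorts.

A patient's observation days are the union over episodes of
`[admit, discharge + 7]`. Exposure days outside all such windows are
clipped away before counting.

Patients with no drug-exposure record in any follow-up window are dropped
by default (`followup_policy = "require-followup-data"`). Requiring
"drug exposure data after discharge" admits more than one reading — no
post-discharge exposure records at all, versus observation ending earlier
than 7 days after discharge — so the policy is a configuration flag, with
the record-based reading as default and `"keep-all"` as the alternative.

## Drug mapping

Two mapping strategies are provided, mirroring how different institutions
hold their vocabularies:

* **dictionary**: a product-code file with one row per product ×
  ingredient (`drug_code`, `ingredient_code`, `atc5`), emulating the
  national EDI product dictionaries that carry ingredient codes per
  product. Fixed-dose combinations appear as multiple rows and contribute
  each constituent ingredient separately to daily counts. Products whose
  rows lack both codes stay unmapped and are excluded, with counts in a
  mapping report (`n_mapped + n_unmapped = n_input_codes` always).
* **vocabulary**: the CDM `concept` / `concept_ancestor` route — a drug
  concept maps to every level-5 ATC concept recorded as its ancestor.
  This path carries no ingredient codes, so the ingredient defaults to the
  ATC5 code itself; where a product has several ATC5 classifications all
  are kept, deduplicated at level 2 for pattern analyses. The two
  strategies produce identical maps on a fixture that encodes the same
  content both ways, which the acceptance suite asserts.

The counting unit is the **ingredient code**, not the product: two
products sharing an ingredient on the same day count once.

## The maximum-count day and its tie-break

For each observation day we form the set of distinct ingredients whose
exposure interval covers it. The patient's summary is the maximum set size
over days; among days attaining the maximum, the day **closest to
admission** wins. For multi-episode patients we interpret "closest to
admission" episode-locally: the distance is measured to the admit date of
the episode containing the day (follow-up days included in the episode's
span), not to the patient's first-ever admission. The two readings
coincide for single-episode patients; the episode-local one matches the
episode framing of the observation-period definition. Any remaining tie
goes to the earlier calendar date, making the selection deterministic.
Exposures with a missing end date are treated as one-day exposures (the
CDM end-date column is nullable and no rule is stated).

## B05 and where the exclusion applies

ATC subgroup B05 (blood substitutes and perfusion solutions) is excluded
from pattern analyses: it is near-universal among inpatients and
uninformative for interaction risk. The exclusion clearly belongs to the
pattern analyses; whether it should also apply to level determination is
an open design choice, resolved here as follows:

* **level determination** (the distribution and summary tables) includes
  B05 by default; `excluded_atc2_counting` makes it configurable;
* **pattern analyses** exclude B05 *before* daily counting, so the
  maximum-count day used for combination keys is determined on the
  excluded exposure set. This makes the accounting exact: every patient
  with a positive maximum contributes exactly one combination key, and
  combination counts per category sum to the category sizes.

Single-subgroup frequencies count a patient once per subgroup used
anywhere in their observation period; combination keys use only the
maximum-count day. The asymmetry is intentional: at-least-once membership
answers which subgroups a category uses at all, while the maximum-count
day captures the regimen at its peak. Pattern populations are restricted to ages 65 and over at study
entry (age = entry year − birth year), while the descriptive tables
stratify 60–69 / 70–79 / ≥ 80; both floors are configuration parameters.

## The synthetic cohort generator

No institutional EHR data can ship with the package, so every stage is
validated on synthetic cohorts with known ground truth.

**Constructive mode** plants, per patient, a target maximum count drawn
from the configured category mix and a target day, then emits exposures
such that the daily distinct-ingredient count equals the target on that
day and is strictly lower everywhere else. The planting is verified
independently in the tests with a brute-force per-day set oracle. Episodes
are emitted either as single visits or as two visits separated by a short
(≤ 20-day) gap, so the merge rule is exercised while the merged structure
stays known by construction (inter-episode gaps exceed 37 days). Each
patient gets at least one exposure in a follow-up window, so the default
eligibility policy retains everyone and planted truth is recoverable for
100% of patients.

**Stochastic mode** draws admission counts (1 + Poisson(0.6), capped at
4), stays (log-normal, median ≈ 7 days, capped at 60), inter-admission
gaps (uniform on 1–60 days, deliberately straddling the 30-day threshold
so about half of consecutive pairs merge), and per-day prescription counts
(Poisson with a per-severity-class intensity). Default dictionary
composition: ~300 products over ~40 ATC2 classes including B05, 10%
without codes, 15% fixed-dose combinations with 2–3 ingredients.

Because the mapping from prescribing intensity to realized category is
stochastic, hitting a target category mix requires calibration:
`calibrate_intensities()` simulates small cohorts on an intensity grid,
estimates the intensity → category confusion matrix, and solves a
non-negative least-squares problem for mixture weights whose induced
category distribution equals the target. With 500 simulated patients per
grid point the fitted mix matches the target to well under a percentage
point, and realized proportions at n = 2000 fall within binomial sampling
error of the target.

The generator emulates the *structural* features the pipeline must handle
— multi-admission patients, gaps on both sides of the merge threshold,
multi-day and combination exposures, unmappable products, post-discharge
prescriptions. It does not emulate clinically realistic drug co-occurrence,
seasonal admission patterns, or institution-specific coding quirks;
passing tests demonstrate algorithmic correctness, not that real-data
prevalences would be reproduced.

## Numerical and formatting choices

* All interval logic is day-granular; dates carry no time component.
* Percentages in the report tables are rounded half-up to one decimal with
  a trailing `.0` dropped (`19`, `49.1`), implemented as
  `floor(10 p + 0.5)/10` with a small epsilon guard against binary float
  artifacts — so identical counts always produce identical percentage
  strings, which the acceptance checks compare byte-for-byte against
  multi-institution reference cells.
* Standard deviations use the n − 1 denominator; strata with fewer than
  two patients report SD as missing.
* Hospitalization period is the summed length of merged episodes
  (discharge − admit + 1), excluding follow-up days.
* Rows with unparseable mandatory dates are dropped with a counted
  warning rather than failing the load; EHR extracts are dirty and a
  counted drop is safer than a hard failure.

## Problem sizes used in the tests

The suite validates the merge rule on 1,000 random ≤ 12-interval
instances against a transitive-closure oracle; daily counting and the
tie-break on 500 random patients (≤ 47 observation days, 30 ingredients,
combinations included) against per-day set materialization; planted-truth
recovery on a 500-patient constructive cohort; and pattern conservation on
a 2,000-patient stochastic cohort. These sizes give complete coverage of
the combinatorial edge cases while keeping the default test run fast.

## Worked example

```{r example, eval = FALSE}
g <- generate_cohort(generator_config(n_patients = 200, seed = 1))
write_bundle(g$bundle, "cohort")
res <- run_pipeline(run_config(input_dir = "cohort", output_dir = "out"))
res$distribution$formatted
res$combo_patterns[category == "excessive polypharmacy"][1:3]
```

## Known limitations

* Ages are year-resolution (entry year − birth year), as in the person
  table; patients can be off by one year around their birthday.
* The vocabulary mapping path counts at ATC5 rather than true ingredient
  granularity; where one ingredient has several ATC5 codes this can
  inflate counts relative to the dictionary path. The equivalence tests
  use fixtures where the two coincide.
* Transfer semantics, death censoring and drug–indication linkage are out
  of scope, as is any association-rule mining beyond frequency ranking.
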