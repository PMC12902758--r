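# Prescribing-pattern mining at the ATC second level (therapeutic
# subgroups): single-class frequencies count patients using a class at
# least once anywhere in their observation period; combination patterns
# take, per patient, the sorted set of classes active on the maximum-count
# day. Both restrict to older adults (>= 65 at study entry) and exclude
# B05 by default.

.age_strata <- c("60-69", "70-79", ">=80")

#' Age at an index date and age stratum
#'
#' Age is computed in whole years as index year minus year of birth (the
#' resolution the person table carries). Strata partition ages 60 and over;
#' younger ages map to `NA`.
#'
#' @param year_of_birth Integer vector.
#' @param index_date Index date(s); the study entry (first admission) in the
#'   pipeline.
#' @return For [compute_age()], integer ages; for [age_stratum()], a factor
#'   with levels `60-69`, `70-79`, `>=80`.
#' @export
compute_age <- function(year_of_birth, index_date) {
  as.integer(format(as.Date(index_date), "%Y")) - as.integer(year_of_birth)
}

#' @rdname compute_age
#' @param age Integer vector of ages in whole years.
#' @export
age_stratum <- function(age) {
  idx <- findInterval(age, c(60, 70, 80))
  idx[idx == 0L] <- NA_integer_
  factor(.age_strata[idx], levels = .age_strata)
}

#' Ages and strata for a cohort at study entry
#'
#' @param person Person table.
#' @param episodes Episodes from [attach_followup()] (provides `entry_date`).
#' @return `data.table` `person_id`, `age`, `stratum`.
#' @export
cohort_ages <- function(person, episodes) {
  person <- as.data.table(person)
  if (any(is.na(person$year_of_birth))) {
    warning("excluding ", sum(is.na(person$year_of_birth)),
            " person(s) with missing year_of_birth")
    person <- person[!is.na(year_of_birth)]
  }
  entries <- as.data.table(episodes)[, .(entry_date = min(admit_date)),
                                     by = person_id]
  out <- person[entries, on = "person_id", nomatch = NULL]
  out[, age := compute_age(year_of_birth, entry_date)]
  out[, stratum := age_stratum(age)]
  out[, .(person_id, age, stratum)]
}

#' Single-class prescribing frequencies per polypharmacy category
#'
#' For each category and ATC level-2 class, the number of patients with at
#' least one exposure of that class anywhere in their observation period;
#' a patient contributes at most once per class. Input exposures should
#' already have excluded classes removed ([exclude_atc2()]); the population
#' is restricted to `min_age` and over at study entry.
#'
#' @param mapped Annotated exposures (post-exclusion).
#' @param assignments Output of [assign_cohort()] on the same exposures.
#' @param ages Output of [cohort_ages()].
#' @param episodes Episodes from [attach_followup()].
#' @param min_age Analysis age floor (default 65).
#' @return `data.table` `category`, `atc2`, `n_patients`.
#' @export
single_frequencies <- function(mapped, assignments, ages, episodes,
                               min_age = 65L) {
  pop <- as.data.table(ages)[age >= min_age, .(person_id)]
  clipped <- clip_to_observation(mapped, episodes)
  membership <- unique(clipped[pop, on = "person_id", nomatch = NULL][
    , .(person_id, atc2)])
  membership <- membership[as.data.table(assignments)[, .(person_id, category)],
                           on = "person_id", nomatch = NULL]
  out <- membership[, .(n_patients = .N), by = .(category, atc2)]
  setorder(out, category, -n_patients, atc2)
  out[]
}

#' Combination patterns on the maximum-count day
#'
#' Each patient with a positive maximum count contributes exactly one
#' combination key: the lexicographically sorted, deduplicated ATC level-2
#' classes among exposures active on their maximum-count day. Rows
#' aggregate patients per (category, key). Assignments must come from the
#' same (excluded) exposures so every contributing patient has a non-empty
#' key.
#'
#' @inheritParams single_frequencies
#' @return `data.table` `category`, `combo_key` (pipe-joined, e.g.
#'   `"A02|C01|N02"`), `n_patients`.
#' @export
combination_patterns <- function(mapped, assignments, ages, episodes,
                                 min_age = 65L) {
  asg <- as.data.table(assignments)
  pop <- as.data.table(ages)[age >= min_age, .(person_id)]
  asg <- asg[pop, on = "person_id", nomatch = NULL][max_count >= 1L]
  di <- daily_ingredients(mapped, episodes)
  active <- di[asg[, .(person_id, date = max_date, category)],
               on = .(person_id, date), nomatch = NULL]
  keys <- active[, .(combo_key = paste(sort(unique(atc2)), collapse = "|")),
                 by = .(person_id, category)]
  out <- keys[, .(n_patients = .N), by = .(category, combo_key)]
  setorder(out, category, -n_patients, combo_key)
  out[]
}

#' Rank pattern rows and keep the top N per category
#'
#' Sorted by patient count descending; ties broken by the lexicographically
#' smaller class/key so rankings are reproducible.
#'
#' @param rows Output of [single_frequencies()] or [combination_patterns()].
#' @param n Rows kept per category (default 10).
#' @return Input rows with a `rank` column, truncated to `n` per category.
#' @export
top_patterns <- function(rows, n = 10L) {
  rows <- copy(as.data.table(rows))
  key_col <- if ("atc2" %in% names(rows)) "atc2" else "combo_key"
  setorderv(rows, c("category", "n_patients", key_col), order = c(1L, -1L, 1L))
  rows[, rank := seq_len(.N), by = category]
  rows[rank <= n][]
}
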