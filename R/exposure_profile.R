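# The polypharmacy metric is the maximum, over a patient's observation days,
# of the number of distinct drug ingredients they are exposed to on a single
# calendar day. The day attaining the maximum (ties broken toward admission)
# anchors the combination-pattern analysis.

.polypharmacy_levels <- c("nonpolypharmacy", "polypharmacy",
                          "major polypharmacy", "excessive polypharmacy")

#' Per-day distinct active ingredients
#'
#' Expands annotated exposures, clipped to observation days, into one row
#' per (person, date, ingredient): an ingredient is active on a date when
#' some exposure of that ingredient covers the date and the date is an
#' observation day. Duplicate products sharing an ingredient on the same day
#' collapse to one row.
#'
#' @param mapped Annotated exposures from [map_exposures()] (must carry
#'   `ingredient_code`; `atc2` is carried through when present).
#' @param episodes Episodes from [attach_followup()].
#' @return `data.table` `person_id`, `date`, `ingredient_code` (and `atc2`),
#'   distinct on (person, date, ingredient[, atc2]).
#' @export
daily_ingredients <- function(mapped, episodes) {
  clipped <- clip_to_observation(mapped, episodes)
  keep_cols <- intersect(c("person_id", "start_date", "end_date",
                           "ingredient_code", "atc2"), names(clipped))
  clipped <- clipped[, keep_cols, with = FALSE]
  if (nrow(clipped) == 0L) {
    out <- data.table(person_id = character(), date = as.Date(character()),
                      ingredient_code = character())
    if ("atc2" %in% keep_cols) out[, atc2 := character()]
    return(out)
  }
  clipped[, row_id := .I]
  days <- clipped[, .(date = seq(start_date, end_date, by = "day")), by = row_id]
  sel <- intersect(c("person_id", "date", "ingredient_code", "atc2"),
                   c(keep_cols, "date"))
  out <- days[clipped, on = "row_id"][, sel, with = FALSE]
  unique(out)
}

#' Daily distinct-ingredient counts over the observation period
#'
#' @param mapped Annotated exposures from [map_exposures()].
#' @param episodes Episodes from [attach_followup()].
#' @return `data.table` `person_id`, `date`, `n_ingredients` (> 0; days with
#'   no active ingredient are absent).
#' @export
daily_counts <- function(mapped, episodes) {
  di <- unique(daily_ingredients(mapped, episodes)[
    , .(person_id, date, ingredient_code)])
  counts <- di[, .(n_ingredients = .N), by = .(person_id, date)]
  setorder(counts, person_id, date)
  counts[]
}

#' Select each patient's maximum-count day with the admission-proximity tie-break
#'
#' The maximum daily count and its date; when several days attain the
#' maximum, the day closest to the admission date of the episode containing
#' it (episode-local distance, follow-up days included in the episode span)
#' wins; remaining ties go to the earliest calendar date. Patients in
#' `episodes` with no counted day get `max_count = 0` and a missing
#' `max_date`.
#'
#' @param counts Output of [daily_counts()].
#' @param episodes Episodes from [attach_followup()].
#' @return `data.table` `person_id`, `max_count`, `max_date`.
#' @export
select_max_day <- function(counts, episodes) {
  eps <- as.data.table(episodes)
  counts <- as.data.table(counts)
  persons <- unique(eps[, .(person_id)])
  if (nrow(counts) == 0L) {
    return(persons[, .(person_id, max_count = 0L, max_date = as.Date(NA))])
  }
  cand <- counts[counts[, .I[n_ingredients == max(n_ingredients)],
                        by = person_id]$V1]
  # locate the episode whose span (admit .. followup_end) contains the day
  cand <- eps[, .(person_id, admit_date, followup_end)][
    cand, on = .(person_id, admit_date <= date, followup_end >= date),
    .(person_id, date = i.date, n_ingredients = i.n_ingredients,
      dist = as.integer(i.date - x.admit_date))]
  setorder(cand, person_id, dist, date)
  best <- cand[, .SD[1L], by = person_id][
    , .(person_id, max_count = as.integer(n_ingredients), max_date = date)]
  out <- best[persons, on = "person_id"]
  out[is.na(max_count), max_count := 0L]
  setorder(out, person_id)
  out[]
}

#' Assign the four-level polypharmacy category
#'
#' The category system for hospitalized older adults: fewer than 5
#' concomitant ingredients is nonpolypharmacy, 5-9 polypharmacy, 10-19 major
#' polypharmacy, and 20 or more excessive polypharmacy.
#'
#' @param max_count Non-negative integer vector of maximum daily
#'   distinct-ingredient counts.
#' @return Ordered factor with levels nonpolypharmacy < polypharmacy <
#'   major polypharmacy < excessive polypharmacy.
#' @export
categorize <- function(max_count) {
  if (any(is.na(max_count)) || any(max_count < 0)) {
    stop("max_count must be non-negative")
  }
  idx <- findInterval(max_count, c(5, 10, 20)) + 1L
  factor(.polypharmacy_levels[idx], levels = .polypharmacy_levels, ordered = TRUE)
}

#' Per-patient polypharmacy assignments for a cohort
#'
#' Runs daily counting, maximum-day selection and categorization over
#' annotated exposures and merged episodes, and adds episode bookkeeping.
#' Deterministic given its inputs and invariant to input row order.
#'
#' @param mapped Annotated exposures from [map_exposures()] (optionally
#'   already filtered by [exclude_atc2()]).
#' @param episodes Episodes from [attach_followup()].
#' @return `data.table` `person_id`, `max_count`, `max_date`, `category`,
#'   `episode_count`, `total_observed_days`.
#' @export
assign_cohort <- function(mapped, episodes) {
  eps <- as.data.table(episodes)
  asg <- select_max_day(daily_counts(mapped, eps), eps)
  book <- eps[, .(episode_count = .N,
                  total_observed_days =
                    sum(as.integer(followup_end - admit_date) + 1L)),
              by = person_id]
  out <- book[asg, on = "person_id"]
  out[, category := categorize(max_count)]
  setorder(out, person_id)
  out[, .(person_id, max_count, max_date, category,
          episode_count, total_observed_days)]
}
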