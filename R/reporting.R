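# Report shapes: a cohort summary (patients, hospitalizations, episodes,
# older adults, distinct therapeutic subgroups), per-age-stratum summary
# statistics of maximum daily drug counts and hospitalization duration, and
# the category x age distribution with column percentages.

#' Format a percentage in the cohort-report style
#'
#' `100 * num / den`, rounded half-up to one decimal, with a trailing
#' `".0"` dropped (so 19.04 prints as `"19"` and 49.13 as `"49.1"`).
#'
#' @param num,den Counts; `den` must be positive.
#' @return Character vector.
#' @export
format_percent <- function(num, den) {
  if (any(den <= 0)) stop("denominator must be positive")
  p <- 100 * num / den
  r <- floor(p * 10 + 0.5 + 1e-9) / 10
  ifelse(abs(r - round(r)) < 1e-9,
         sprintf("%d", as.integer(round(r))),
         sprintf("%.1f", r))
}

#' Distribution of patients by polypharmacy level and age stratum
#'
#' Cross-tabulates age strata (rows) against polypharmacy categories
#' (columns); each cell shows the patient count with the percentage of the
#' category column total. Patients below 60 are omitted (the strata cover
#' 60 and over). Categories with no patients are omitted with a note.
#'
#' @param assignments Output of [assign_cohort()].
#' @param ages Output of [cohort_ages()].
#' @return A list: `counts` (stratum x category integer matrix including a
#'   `Total` row), `formatted` (`data.table` of `"n (pct)"` cells),
#'   `omitted` (empty categories).
#' @export
distribution_table <- function(assignments, ages) {
  dt <- as.data.table(assignments)[as.data.table(ages), on = "person_id",
                                   nomatch = NULL]
  dt <- dt[!is.na(stratum)]
  counts <- table(stratum = dt$stratum, category = dt$category)
  totals <- colSums(counts)
  omitted <- colnames(counts)[totals == 0L]
  if (length(omitted)) {
    message("omitting empty categor", if (length(omitted) > 1L) "ies" else "y",
            ": ", paste(omitted, collapse = ", "))
  }
  keep <- totals > 0L
  counts <- counts[, keep, drop = FALSE]
  totals <- totals[keep]
  fmt <- data.table(stratum = rownames(counts))
  for (cc in colnames(counts)) {
    fmt[[cc]] <- sprintf("%d (%s)", counts[, cc],
                         format_percent(counts[, cc], totals[cc]))
  }
  total_row <- as.list(c(stratum = "Total",
                         sprintf("%d (100)", as.integer(totals))))
  names(total_row) <- c("stratum", colnames(counts))
  fmt <- rbind(fmt, as.data.table(total_row))
  count_mat <- rbind(unclass(counts), Total = as.integer(totals))
  list(counts = count_mat, formatted = fmt, omitted = omitted)
}

#' Per-stratum summary of maximum drug counts and hospitalization duration
#'
#' Mean and SD (n - 1 denominator) of the maximum daily drug-ingredient
#' count and of the hospitalization period per age stratum. Hospitalization
#' period is the summed length of merged inpatient episodes
#' (discharge - admit + 1 per episode), excluding follow-up days. Strata
#' with fewer than 2 patients report SD as `NA`.
#'
#' @param assignments Output of [assign_cohort()].
#' @param episodes Episodes from [attach_followup()].
#' @param ages Output of [cohort_ages()].
#' @return `data.table`: `stratum`, `n`, `drugs_mean`, `drugs_sd`,
#'   `stay_mean`, `stay_sd`.
#' @export
summary_stats <- function(assignments, episodes, ages) {
  stay <- as.data.table(episodes)[
    , .(stay_days = sum(as.integer(discharge_date - admit_date) + 1L)),
    by = person_id]
  dt <- as.data.table(assignments)[as.data.table(ages), on = "person_id",
                                   nomatch = NULL]
  dt <- dt[!is.na(stratum)][stay, on = "person_id", nomatch = NULL]
  out <- dt[, .(n = .N,
                drugs_mean = mean(max_count),
                drugs_sd = if (.N > 1L) sd(max_count) else NA_real_,
                stay_mean = mean(stay_days),
                stay_sd = if (.N > 1L) sd(stay_days) else NA_real_),
            keyby = stratum]
  out[]
}

#' Cohort-level summary counts
#'
#' Reports the headline cohort characteristics: total patients, patients
#' hospitalized in the study window, hospitalization events (both raw
#' inpatient visits and post-merge episodes), older hospitalized adults
#' (>= 60 at entry) with the percentage of all patients, and the number of
#' distinct ATC level-2 subgroups prescribed.
#'
#' @param person Person table.
#' @param admissions Raw admissions from [extract_admissions()].
#' @param episodes Merged episodes from [attach_followup()].
#' @param mapped Annotated exposures from [map_exposures()].
#' @param ages Output of [cohort_ages()].
#' @return Named list of counts and formatted percentages.
#' @export
cohort_summary <- function(person, admissions, episodes, mapped, ages) {
  person <- as.data.table(person)
  n_patients <- length(unique(person$person_id))
  hosp <- unique(as.data.table(admissions)$person_id)
  ages <- as.data.table(ages)
  n_older <- ages[person_id %in% hosp & age >= 60L, .N]
  list(
    n_patients = n_patients,
    n_hospitalized = length(hosp),
    pct_hospitalized = format_percent(length(hosp), n_patients),
    n_admission_visits = nrow(as.data.table(admissions)),
    n_episodes = nrow(as.data.table(episodes)),
    n_older_hospitalized = n_older,
    pct_older_hospitalized = format_percent(n_older, n_patients),
    n_distinct_atc2 = length(unique(as.data.table(mapped)$atc2))
  )
}
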