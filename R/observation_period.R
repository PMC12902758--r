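# Observation periods follow the study design for hospitalized cohorts:
# consecutive admissions separated by <= 30 days collapse into one continuous
# admission episode, and each episode is followed for 7 calendar days after
# discharge to capture outpatient prescriptions at the transition of care.

#' Extract sorted inpatient intervals within the study window
#'
#' Keeps inpatient visits whose admission date falls inside the study window
#' and returns them sorted per person by (admission, discharge). Zero-length
#' stays (admit == discharge) are retained as one-day intervals.
#'
#' @param visits `data.table` of visit records (`person_id`, `visit_id`,
#'   `visit_kind`, `start_date`, `end_date`).
#' @param study_start,study_end Study window bounds (dates or ISO strings);
#'   defaults 2012-01-01 .. 2020-12-31.
#' @return `data.table` with `person_id`, `visit_id`, `admit_date`,
#'   `discharge_date`, sorted.
#' @export
extract_admissions <- function(visits, study_start = "2012-01-01",
                               study_end = "2020-12-31") {
  visits <- as.data.table(visits)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  adm <- visits[visit_kind == "inpatient" &
                  start_date >= study_start & start_date <= study_end,
                .(person_id, visit_id, admit_date = start_date,
                  discharge_date = end_date)]
  setorder(adm, person_id, admit_date, discharge_date)
  adm[]
}

#' Merge admissions separated by at most `gap_days` into continuous episodes
#'
#' Two consecutive admissions of the same patient merge when the next
#' admission starts within `gap_days` days of the previous discharge
#' (inclusive); overlapping or nested intervals always merge. Merging is
#' transitive, so chains of close admissions collapse into one episode
#' spanning the earliest admission to the latest discharge. The operation is
#' idempotent and the episode count is non-increasing in `gap_days`.
#'
#' @param admissions Output of [extract_admissions()] (or any table with
#'   `person_id`, `admit_date`, `discharge_date`, optionally `visit_id`).
#' @param gap_days Merge threshold in whole days (default 30).
#' @return `data.table` of episodes: `person_id`, `admit_date`,
#'   `discharge_date`, `n_visits`, `source_visit_ids` (pipe-joined).
#' @export
merge_admissions <- function(admissions, gap_days = 30L) {
  adm <- as.data.table(admissions)
  if (!"visit_id" %in% names(adm)) adm[, visit_id := NA_character_]
  if (nrow(adm) == 0L) {
    return(data.table(person_id = character(), admit_date = as.Date(character()),
                      discharge_date = as.Date(character()), n_visits = integer(),
                      source_visit_ids = character()))
  }
  adm <- adm[order(person_id, admit_date, discharge_date)]
  # sweep: a new episode starts when the gap to the running maximum discharge
  # exceeds gap_days; cummax over the integer representation keeps nested
  # intervals inside the running episode
  adm[, episode_id := {
    a <- as.integer(admit_date)
    d <- cummax(as.integer(discharge_date))
    new_ep <- c(TRUE, a[-1L] - d[-length(d)] > gap_days)
    cumsum(new_ep)
  }, by = person_id]
  eps <- adm[, .(
    admit_date = min(admit_date),
    discharge_date = max(discharge_date),
    n_visits = .N,
    source_visit_ids = paste(visit_id, collapse = "|")
  ), by = .(person_id, episode_id)]
  eps[, episode_id := NULL]
  setorder(eps, person_id, admit_date)
  eps[]
}

#' Attach the post-discharge follow-up window to merged episodes
#'
#' Each episode gains a follow-up window covering the `followup_days`
#' calendar days after discharge (half-open: the discharge day belongs to
#' the stay, days discharge+1 .. discharge+followup_days to follow-up). A
#' patient's observation days are the union over episodes of
#' \[admit, discharge + followup_days\]. Because episodes are separated by
#' more than the merge gap (30 > 7), follow-up windows never reach the next
#' episode.
#'
#' @param episodes Output of [merge_admissions()].
#' @param followup_days Length of the follow-up window (default 7).
#' @return `data.table` of episodes with added `followup_end` and per-person
#'   `entry_date` (first admission = study entry).
#' @export
attach_followup <- function(episodes, followup_days = 7L) {
  eps <- copy(as.data.table(episodes))
  eps[, followup_end := discharge_date + followup_days]
  eps[, entry_date := min(admit_date), by = person_id]
  setattr(eps, "followup_days", as.integer(followup_days))
  eps[]
}

#' Flag patients by post-discharge drug-exposure availability
#'
#' Under the `"require-followup-data"` policy (default), a patient is
#' dropped when no drug-exposure record falls within any of their follow-up
#' windows — the operationalization of excluding patients without drug
#' exposure data after discharge. `"keep-all"` retains everyone.
#'
#' @param episodes Episodes with follow-up from [attach_followup()].
#' @param exposures Drug exposures for the same persons (`person_id`,
#'   `start_date`, optional `end_date`).
#' @param policy `"require-followup-data"` or `"keep-all"`.
#' @return `data.table` `person_id`, `keep` (logical), one row per person in
#'   `episodes`.
#' @export
eligibility_filter <- function(episodes, exposures,
                               policy = c("require-followup-data", "keep-all")) {
  policy <- match.arg(policy)
  eps <- as.data.table(episodes)
  persons <- unique(eps[, .(person_id)])
  if (policy == "keep-all") return(persons[, .(person_id, keep = TRUE)])
  exp <- copy(as.data.table(exposures))
  if (!"end_date" %in% names(exp)) exp[, end_date := as.Date(NA)]
  exp[is.na(end_date), end_date := start_date]
  # exposure intersects the follow-up window (discharge, discharge+f]
  hit <- exp[eps, on = .(person_id), allow.cartesian = TRUE, nomatch = NULL][
    end_date > discharge_date & start_date <= followup_end,
    unique(person_id)]
  persons[, .(person_id, keep = person_id %in% hit)]
}

#' Clip exposures to a patient's observation days
#'
#' Intersects each exposure interval with each episode window
#' \[admit, followup_end\]; portions outside all windows are discarded.
#'
#' @param exposures Exposure table (`person_id`, `start_date`, `end_date`,
#'   plus any annotation columns, which are carried through).
#' @param episodes Episodes from [attach_followup()].
#' @return `data.table` of clipped exposures with `start_date`/`end_date`
#'   replaced by the clipped bounds.
#' @export
clip_to_observation <- function(exposures, episodes) {
  exp <- copy(as.data.table(exposures))
  if (!"end_date" %in% names(exp)) exp[, end_date := as.Date(NA)]
  exp[is.na(end_date), end_date := start_date]
  eps <- as.data.table(episodes)[, .(person_id, admit_date, followup_end)]
  out <- exp[eps, on = .(person_id), allow.cartesian = TRUE, nomatch = NULL]
  out <- out[start_date <= followup_end & end_date >= admit_date]
  out[, `:=`(start_date = pmax(start_date, admit_date),
             end_date = pmin(end_date, followup_end))]
  out[, c("admit_date", "followup_end") := NULL]
  out[]
}
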