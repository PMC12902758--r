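# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive set materialization / pairwise closure so they
# share no code path with the package implementation.

library(data.table)

# --- fixture builders -------------------------------------------------------

mk_visits <- function(person_id, starts, ends, kind = "inpatient") {
  data.table(person_id = person_id,
             visit_id = paste0(person_id, "-", seq_along(starts)),
             visit_kind = kind,
             start_date = as.Date(starts), end_date = as.Date(ends))
}

mk_exposures <- function(person_id, drug, starts, ends = starts) {
  data.table(person_id = person_id, drug_code = drug,
             start_date = as.Date(starts), end_date = as.Date(ends))
}

mk_dict <- function(drug, ingredient, atc5) {
  data.table(drug_code = drug, ingredient_code = ingredient, atc5 = atc5)
}

# annotated exposure rows as map_exposures() would emit them
mk_annotated <- function(person_id, ingredient, starts, ends = starts,
                         atc2 = "J01") {
  data.table(person_id = person_id, ingredient_code = ingredient,
             atc2 = atc2, start_date = as.Date(starts),
             end_date = as.Date(ends))
}

mk_episodes <- function(person_id, admits, discharges, followup_days = 7L) {
  dt <- data.table(person_id = person_id,
                   admit_date = as.Date(admits),
                   discharge_date = as.Date(discharges))
  dt[, followup_end := discharge_date + followup_days]
  dt[, entry_date := min(admit_date), by = person_id]
  dt
}

# random admission intervals for one person within a ~2-year span
rand_intervals <- function(n, seed = NULL, origin = as.Date("2014-01-01")) {
  if (!is.null(seed)) set.seed(seed)
  starts <- origin + sample(0:600, n, replace = TRUE)
  lens <- sample(0:20, n, replace = TRUE)
  data.table(person_id = "p1",
             visit_id = paste0("v", seq_len(n)),
             admit_date = starts, discharge_date = starts + lens)
}

# --- oracles ----------------------------------------------------------------

# transitive-closure merge: union-find over all interval pairs whose gap
# (in either order) is <= gap_days; components become episodes
oracle_merge <- function(intervals, gap_days = 30L) {
  dt <- as.data.table(intervals)
  out <- list()
  for (pid in unique(dt$person_id)) {
    x <- dt[person_id == pid]
    n <- nrow(x)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      gap <- as.integer(max(x$admit_date[i], x$admit_date[j]) -
                          min(x$discharge_date[i], x$discharge_date[j]))
      if (gap <= gap_days) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    eps <- x[, .(admit_date = min(admit_date),
                 discharge_date = max(discharge_date)), by = .(root = roots)]
    eps[, person_id := pid]
    out[[pid]] <- eps[, .(person_id, admit_date, discharge_date)]
  }
  res <- rbindlist(out)
  setorder(res, person_id, admit_date)
  res[]
}

# naive per-day set materialization of distinct ingredients
oracle_daily <- function(annotated, episodes) {
  ann <- as.data.table(annotated)
  eps <- as.data.table(episodes)
  out <- list()
  for (pid in unique(eps$person_id)) {
    e <- eps[person_id == pid]
    obs <- unique(unlist(lapply(seq_len(nrow(e)), function(i) {
      as.integer(seq(e$admit_date[i], e$followup_end[i], by = "day"))
    })))
    a <- ann[person_id == pid]
    sets <- list()
    for (r in seq_len(nrow(a))) {
      for (d in as.integer(a$start_date[r]):as.integer(a$end_date[r])) {
        if (d %in% obs) {
          key <- as.character(d)
          sets[[key]] <- union(sets[[key]], a$ingredient_code[r])
        }
      }
    }
    if (length(sets)) {
      out[[pid]] <- data.table(
        person_id = pid,
        date = as.Date(as.integer(names(sets)), origin = "1970-01-01"),
        n_ingredients = vapply(sets, length, integer(1)))
    }
  }
  if (!length(out)) {
    return(data.table(person_id = character(), date = as.Date(character()),
                      n_ingredients = integer()))
  }
  res <- rbindlist(out)
  setorder(res, person_id, date)
  res[]
}

# literal tie-break: max count, then min distance to the admit date of the
# containing episode, then earliest date
oracle_max_day <- function(daily, episodes) {
  eps <- as.data.table(episodes)
  out <- list()
  for (pid in unique(eps$person_id)) {
    d <- as.data.table(daily)[person_id == pid]
    if (nrow(d) == 0L) {
      out[[pid]] <- data.table(person_id = pid, max_count = 0L,
                               max_date = as.Date(NA))
      next
    }
    mx <- max(d$n_ingredients)
    cand <- d[n_ingredients == mx]
    e <- eps[person_id == pid]
    dist <- vapply(seq_len(nrow(cand)), function(i) {
      dd <- cand$date[i]
      hit <- e[admit_date <= dd & followup_end >= dd]
      min(as.integer(dd - hit$admit_date))
    }, integer(1))
    ord <- order(dist, cand$date)
    out[[pid]] <- data.table(person_id = pid, max_count = as.integer(mx),
                             max_date = cand$date[ord[1L]])
  }
  res <- rbindlist(out)
  setorder(res, person_id)
  res[]
}

# random annotated exposures for one patient over their episodes
rand_patient <- function(pid, n_exposures = 50L, n_ingredients = 30L,
                         combo_prob = 0.2) {
  admit <- as.Date("2015-03-01") + sample(0:200, 1L)
  stay <- sample(5:40, 1L)
  eps <- mk_episodes(pid, admit, admit + stay)
  span0 <- as.integer(admit) - 5L  # some exposures start before admission
  span1 <- as.integer(eps$followup_end) + 5L
  rows <- list()
  for (r in seq_len(n_exposures)) {
    k <- if (runif(1) < combo_prob) sample(2:3, 1L) else 1L
    ings <- sprintf("I%02d", sample.int(n_ingredients, k))
    s <- sample(span0:span1, 1L)
    e <- min(s + sample(0:8, 1L), span1)
    rows[[r]] <- data.table(person_id = pid, ingredient_code = ings,
                            atc2 = "J01",
                            start_date = as.Date(s, origin = "1970-01-01"),
                            end_date = as.Date(e, origin = "1970-01-01"))
  }
  list(episodes = eps, annotated = rbindlist(rows))
}
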