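# Synthetic CDM-shaped cohorts with known ground truth. Constructive mode
# plants, per patient, a unique maximum-count day whose distinct-ingredient
# count and category are known exactly; stochastic mode draws admissions,
# stays, gaps and prescriptions from configured distributions to exercise
# the merge rule and the pattern invariants at scale.

#' Default configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients.
#' @param seed Integer RNG seed; the same seed reproduces the bundle exactly.
#' @param age_weights Sampling weights over entry-age bands
#'   `20-59, 60-69, 70-79, >=80`. Default emphasizes older inpatients.
#' @param admissions_lambda Mean of the Poisson part of the per-patient
#'   admission count (`1 + Poisson(lambda)`).
#' @param los_meanlog,los_sdlog Log-normal parameters of length of stay in
#'   days (rounded up); defaults give a median of about 7 days and a long
#'   right tail, as typical of inpatient stays.
#' @param gap_min,gap_max Integer bounds of the uniform inter-admission gap
#'   in days used by stochastic mode; the default 1..60 straddles the 30-day
#'   merge threshold so roughly half of consecutive admission pairs merge.
#' @param level_mix Target proportions over the four polypharmacy
#'   categories (must sum to 1). The default mirrors a hospitalized older
#'   cohort where major polypharmacy is the modal level.
#' @param daily_rx_intensity Named per-category daily prescription rates
#'   used by stochastic mode (new prescriptions per observation day).
#' @param frac_unmapped_drugs Fraction of dictionary products lacking
#'   ATC/ingredient codes (these never map and are excluded upstream).
#' @param frac_combination_products Fraction of mapped products that are
#'   fixed-dose combinations (2-3 ingredients).
#' @param split_prob Probability that a constructive-mode episode is emitted
#'   as two raw visits separated by a short (<= 20 day) gap, exercising the
#'   merge rule.
#' @return Named list of class `polyrx_config`.
#' @export
generator_config <- function(n_patients = 100L,
                             seed = 1L,
                             age_weights = c("20-59" = 0.15, "60-69" = 0.30,
                                             "70-79" = 0.35, ">=80" = 0.20),
                             admissions_lambda = 0.6,
                             los_meanlog = 2.0,
                             los_sdlog = 0.6,
                             gap_min = 1L,
                             gap_max = 60L,
                             level_mix = c(nonpolypharmacy = 0.10,
                                           polypharmacy = 0.20,
                                           `major polypharmacy` = 0.40,
                                           `excessive polypharmacy` = 0.30),
                             daily_rx_intensity = c(nonpolypharmacy = 0.35,
                                                    polypharmacy = 1.2,
                                                    `major polypharmacy` = 3.0,
                                                    `excessive polypharmacy` = 7.0),
                             frac_unmapped_drugs = 0.10,
                             frac_combination_products = 0.15,
                             split_prob = 0.35) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              age_weights = age_weights, admissions_lambda = admissions_lambda,
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              gap_min = as.integer(gap_min), gap_max = as.integer(gap_max),
              level_mix = level_mix, daily_rx_intensity = daily_rx_intensity,
              frac_unmapped_drugs = frac_unmapped_drugs,
              frac_combination_products = frac_combination_products,
              split_prob = split_prob)
  validate_config(cfg)
  structure(cfg, class = "polyrx_config")
}

validate_config <- function(cfg) {
  if (cfg$n_patients < 0L) stop("n_patients must be non-negative")
  if (abs(sum(cfg$level_mix) - 1) > 1e-9) stop("level_mix must sum to 1")
  fr <- c(cfg$frac_unmapped_drugs, cfg$frac_combination_products, cfg$split_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(cfg$age_weights < 0) || sum(cfg$age_weights) <= 0) {
    stop("age_weights must be non-negative with positive sum")
  }
  if (!setequal(names(cfg$level_mix), .polypharmacy_levels)) {
    stop("level_mix must be named by the four polypharmacy categories")
  }
  invisible(cfg)
}

#' Synthetic drug-code dictionary
#'
#' Builds a product-code dictionary of ~`n_products` fake products spread
#' over `n_atc2` ATC second-level classes (B05 and other common inpatient
#' classes always included), with a configurable fraction of codeless
#' (unmappable) products and of fixed-dose combinations carrying 2-3
#' ingredients. Ingredient codes are unique per (product, constituent), so
#' distinct products never share an ingredient — which keeps planted daily
#' counts exact in constructive mode.
#'
#' @param n_products Number of products.
#' @param n_atc2 Number of ATC level-2 classes to draw from.
#' @param frac_unmapped Fraction of products emitted with blank codes.
#' @param frac_combination Fraction of mapped products with 2-3 ingredients.
#' @return Dictionary `data.table` (`drug_code`, `ingredient_code`, `atc5`);
#'   rows of unmapped products carry empty strings.
#' @export
synthetic_dictionary <- function(n_products = 300L, n_atc2 = 40L,
                                 frac_unmapped = 0.10,
                                 frac_combination = 0.15) {
  core <- c("A02", "A03", "A06", "A10", "B01", "B05", "C01", "C10",
            "H02", "J01", "M01", "N01", "N02", "N05", "R05", "S01")
  extra_n <- max(0L, n_atc2 - length(core))
  pool <- setdiff(
    as.vector(outer(LETTERS[c(1:5, 7:14)], sprintf("%02d", 1:16), paste0)),
    core)
  atc2s <- c(core, sample(pool, extra_n))[seq_len(max(n_atc2, length(core)))]
  atc2s <- atc2s[!is.na(atc2s)]
  rows <- vector("list", n_products)
  ing_counter <- 0L
  for (i in seq_len(n_products)) {
    code <- sprintf("P%04d", i)
    if (runif(1) < frac_unmapped) {
      rows[[i]] <- data.table(drug_code = code, ingredient_code = "", atc5 = "")
      next
    }
    k <- if (runif(1) < frac_combination) sample(2:3, 1L) else 1L
    cls <- sample(atc2s, 1L)
    ings <- sprintf("I%05d", ing_counter + seq_len(k))
    ing_counter <- ing_counter + k
    atc5 <- paste0(cls, paste0(sample(LETTERS, k, replace = TRUE),
                               sample(LETTERS, k, replace = TRUE)),
                   sprintf("%02d", sample(1:99, k, replace = TRUE)))
    rows[[i]] <- data.table(drug_code = code, ingredient_code = ings, atc5 = atc5)
  }
  rbindlist(rows)
}

# episode skeletons for one patient: raw visits plus the merged structure
# known by construction (intra-episode gaps <= 20, inter-episode gaps > 37)
.skeleton <- function(pid, entry_year, cfg, mode) {
  n_epi <- 1L + rpois(1L, cfg$admissions_lambda)
  n_epi <- min(n_epi, 4L)
  visits <- list()
  episodes <- list()
  cur <- as.Date(sprintf("%d-01-01", entry_year)) + sample(0:300, 1L)
  vid <- 0L
  for (e in seq_len(n_epi)) {
    los_draw <- function() min(ceiling(rlnorm(1, cfg$los_meanlog, cfg$los_sdlog)), 60)
    if (mode == "constructive" && runif(1) < cfg$split_prob) {
      l1 <- los_draw()
      l2 <- los_draw()
      g <- sample(1:20, 1L)
      s1 <- cur; e1 <- s1 + l1 - 1L
      s2 <- e1 + g; e2 <- s2 + l2 - 1L
      visits[[length(visits) + 1L]] <- data.table(
        person_id = pid, visit_id = paste0(pid, "-v", vid + 1:2),
        visit_kind = "inpatient",
        start_date = c(s1, s2), end_date = c(e1, e2))
      vid <- vid + 2L
      episodes[[e]] <- data.table(person_id = pid, admit_date = s1,
                                  discharge_date = e2)
      cur <- e2
    } else {
      los <- los_draw()
      s1 <- cur; e1 <- s1 + los - 1L
      visits[[length(visits) + 1L]] <- data.table(
        person_id = pid, visit_id = paste0(pid, "-v", vid + 1L),
        visit_kind = "inpatient", start_date = s1, end_date = e1)
      vid <- vid + 1L
      episodes[[e]] <- data.table(person_id = pid, admit_date = s1,
                                  discharge_date = e1)
      cur <- e1
    }
    gap <- if (mode == "constructive") sample(45:120, 1L)
           else sample(cfg$gap_min:cfg$gap_max, 1L)
    cur <- cur + gap
  }
  list(visits = rbindlist(visits), episodes = rbindlist(episodes))
}

#' Plant an exposure profile attaining a target maximum count on a target day
#'
#' Emits exposure records whose per-day distinct-ingredient count equals
#' `target_max_count` on `target_date` and is strictly lower on every other
#' observation day — the inverse of the daily-counting stage, used to build
#' cohorts with known category ground truth. A background of multi-day
#' single- and combination-product exposures is laid down under a per-day
#' cap of `target_max_count - 1`, at least one outpatient exposure is placed
#' in the first follow-up window, and the target day is topped up exactly.
#'
#' @param episodes Merged episodes of one patient (`admit_date`,
#'   `discharge_date`; follow-up of 7 days is assumed).
#' @param target_max_count Planted maximum (>= 1).
#' @param target_date Planted maximum day; must be an observation day. When
#'   `target_max_count == 1` it must lie in a follow-up window (no other day
#'   may carry an exposure).
#' @param products List of mapped products: `singles` and `combos`
#'   `data.table`s (`drug_code`, k = ingredients per product), plus
#'   `unmapped` drug codes.
#' @param frac_combination Probability a background exposure uses a
#'   combination product.
#' @return `data.table` of exposure records (`person_id`, `drug_code`,
#'   `start_date`, `end_date`).
#' @export
plant_profile <- function(episodes, target_max_count, target_date, products,
                          frac_combination = 0.15) {
  stopifnot(target_max_count >= 1L)
  eps <- copy(as.data.table(episodes))
  eps[, followup_end := discharge_date + 7L]
  obs <- eps[, unlist(lapply(seq_len(.N), function(i) {
    as.integer(seq(admit_date[i], followup_end[i], by = "day"))
  }))]
  obs <- sort(unique(obs))
  tgt <- as.integer(as.Date(target_date))
  if (!(tgt %in% obs)) stop("target_date must be an observation day")
  pid <- eps$person_id[1L]
  counts <- setNames(integer(length(obs)), obs)
  cap <- setNames(rep(target_max_count - 1L, length(obs)), obs)
  cap[as.character(tgt)] <- target_max_count

  avail_single <- sample(products$singles$drug_code)
  avail_combo <- if (nrow(products$combos)) sample(products$combos$drug_code)
                 else character()
  combo_k <- setNames(products$combos$k, products$combos$drug_code)
  take_single <- function() {
    if (!length(avail_single)) stop("dictionary too small for planted profile")
    d <- avail_single[1L]; avail_single <<- avail_single[-1L]; d
  }
  out <- list()
  emit <- function(drug, s, e) {
    out[[length(out) + 1L]] <<- data.table(
      person_id = pid, drug_code = drug,
      start_date = as.Date(s, origin = "1970-01-01"),
      end_date = as.Date(e, origin = "1970-01-01"))
  }

  fu_day <- as.integer(eps$discharge_date[1L]) + 1L
  if (target_max_count == 1L) {
    in_followup <- any(tgt > as.integer(eps$discharge_date) &
                         tgt <= as.integer(eps$followup_end))
    if (!in_followup) {
      stop("with target_max_count = 1 the target_date must fall in a follow-up window")
    }
    emit(take_single(), tgt, tgt)
    return(rbindlist(out))
  }
  # guarantee post-discharge exposure data (eligibility requirement)
  emit(take_single(), fu_day, fu_day)
  counts[as.character(fu_day)] <- 1L

  n_attempts <- rpois(1L, 0.25 * length(obs)) + 2L
  for (a in seq_len(n_attempts)) {
    use_combo <- length(avail_combo) > 0L && runif(1) < frac_combination
    k <- if (use_combo) combo_k[[avail_combo[1L]]] else 1L
    ep <- eps[sample(.N, 1L)]
    span0 <- as.integer(ep$admit_date)
    span1 <- as.integer(ep$followup_end)
    s <- sample(span0:span1, 1L)
    e <- min(s + sample(0:6, 1L), span1)
    days <- as.character(s:e)
    if (all(counts[days] + k <= cap[days])) {
      if (use_combo) {
        emit(avail_combo[1L], s, e)
        avail_combo <- avail_combo[-1L]
      } else {
        emit(take_single(), s, e)
      }
      counts[days] <- counts[days] + k
    }
  }
  tkey <- as.character(tgt)
  while (counts[tkey] < target_max_count) {
    emit(take_single(), tgt, tgt)
    counts[tkey] <- counts[tkey] + 1L
  }
  # sprinkle unmapped products; they are excluded at mapping and do not count
  if (length(products$unmapped) && length(obs)) {
    for (u in sample(products$unmapped,
                     min(length(products$unmapped), sample(0:2, 1L)))) {
      d <- sample(obs, 1L)
      emit(u, d, d)
    }
  }
  rbindlist(out)
}

.category_count_range <- list(
  nonpolypharmacy = 1:4, polypharmacy = 5:9,
  `major polypharmacy` = 10:19, `excessive polypharmacy` = 20:26
)

#' Generate a synthetic CDM bundle
#'
#' Constructive mode plants, for every patient, a known maximum daily
#' distinct-ingredient count attained on exactly one known day, so the full
#' pipeline can be validated against planted truth. Stochastic mode draws
#' prescriptions from per-category daily intensities and inter-admission
#' gaps straddling the 30-day merge threshold, for property-style testing
#' at scale. Both modes are deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param mode `"constructive"` or `"stochastic"`.
#' @param calibration Optional output of [calibrate_intensities()]; in
#'   stochastic mode, per-patient intensities are then drawn from the
#'   calibrated mixture instead of the per-category defaults.
#' @return List with `bundle` (tables `person`, `visit_occurrence`,
#'   `drug_exposure`, `dictionary`) and `truth` (`data.table` per patient:
#'   `person_id`, `max_count`, `max_date`, `category`, `n_episodes`;
#'   `NULL` in stochastic mode).
#' @export
generate_cohort <- function(config = generator_config(),
                            mode = c("constructive", "stochastic"),
                            calibration = NULL) {
  mode <- match.arg(mode)
  validate_config(config)
  set.seed(config$seed)
  dict <- synthetic_dictionary(
    frac_unmapped = config$frac_unmapped_drugs,
    frac_combination = config$frac_combination_products)
  mapped_rows <- dict[ingredient_code != ""]
  per_prod <- mapped_rows[, .(k = .N), by = drug_code]
  products <- list(
    singles = per_prod[k == 1L],
    combos = per_prod[k > 1L],
    unmapped = unique(dict[ingredient_code == "", drug_code])
  )
  n <- config$n_patients
  if (n == 0L) {
    return(list(bundle = list(person = empty_cdm_table("person"),
                              visit_occurrence = empty_cdm_table("visit_occurrence"),
                              drug_exposure = empty_cdm_table("drug_exposure"),
                              dictionary = dict),
                truth = data.table(person_id = character(),
                                   max_count = integer(),
                                   max_date = as.Date(character()),
                                   category = factor(character(),
                                                     levels = .polypharmacy_levels,
                                                     ordered = TRUE),
                                   n_episodes = integer())))
  }
  ages_band <- sample(names(config$age_weights), n, replace = TRUE,
                      prob = config$age_weights)
  age_from_band <- function(b) switch(b, "20-59" = sample(20:59, 1L),
                                      "60-69" = sample(60:69, 1L),
                                      "70-79" = sample(70:79, 1L),
                                      ">=80" = sample(80:95, 1L))
  cats <- sample(names(config$level_mix), n, replace = TRUE,
                 prob = config$level_mix)
  persons <- vector("list", n)
  visits <- vector("list", n)
  exposures <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("p%05d", i)
    # later episodes of a multi-admission patient must stay inside the
    # default study window, so entries stop well before its end
    entry_year <- sample(2012:2017, 1L)
    age <- age_from_band(ages_band[i])
    persons[[i]] <- data.table(person_id = pid,
                               year_of_birth = entry_year - age,
                               gender = sample(c("male", "female"), 1L))
    sk <- .skeleton(pid, entry_year, config, mode)
    visits[[i]] <- sk$visits
    eps <- sk$episodes
    if (mode == "constructive") {
      target <- sample(.category_count_range[[cats[i]]], 1L)
      eps[, followup_end := discharge_date + 7L]
      if (target == 1L) {
        ep <- eps[sample(.N, 1L)]
        tgt <- ep$discharge_date + sample(1:7, 1L)
      } else {
        ep <- eps[sample(.N, 1L)]
        tgt <- ep$admit_date +
          sample(0:as.integer(ep$followup_end - ep$admit_date), 1L)
      }
      exposures[[i]] <- plant_profile(
        eps[, .(person_id, admit_date, discharge_date)], target, tgt,
        products, config$frac_combination_products)
      truth[[i]] <- data.table(person_id = pid, max_count = as.integer(target),
                               max_date = as.Date(tgt),
                               category = cats[i], n_episodes = nrow(eps))
    } else {
      intensity <- if (!is.null(calibration)) {
        calibration$grid[sample.int(length(calibration$grid), 1L,
                                    prob = calibration$weights)]
      } else {
        config$daily_rx_intensity[[cats[i]]]
      }
      exposures[[i]] <- .stochastic_exposures(
        pid, eps, products, intensity, config$frac_combination_products)
    }
  }
  bundle <- list(
    person = rbindlist(persons),
    visit_occurrence = rbindlist(visits),
    drug_exposure = rbindlist(exposures)[, .(person_id, drug_code,
                                             start_date, end_date)],
    dictionary = dict
  )
  truth_dt <- if (mode == "constructive") {
    tr <- rbindlist(truth)
    tr[, category := factor(category, levels = .polypharmacy_levels,
                            ordered = TRUE)]
    tr[]
  } else NULL
  list(bundle = bundle, truth = truth_dt)
}

.stochastic_exposures <- function(pid, eps, products, intensity,
                                  frac_combination) {
  out <- list()
  all_drugs <- c(products$singles$drug_code, products$combos$drug_code)
  n_combo <- nrow(products$combos)
  n_single <- nrow(products$singles)
  for (e in seq_len(nrow(eps))) {
    s0 <- as.integer(eps$admit_date[e])
    s1 <- as.integer(eps$discharge_date[e]) + 7L
    span <- s1 - s0 + 1L
    n_rx <- rpois(1L, intensity * span)
    if (n_rx == 0L && runif(1) < 0.9) n_rx <- 1L
    if (n_rx == 0L) next
    use_combo <- runif(n_rx) < frac_combination & n_combo > 0L
    drug <- ifelse(use_combo,
                   products$combos$drug_code[sample.int(max(n_combo, 1L), n_rx,
                                                        replace = TRUE)],
                   products$singles$drug_code[sample.int(n_single, n_rx,
                                                         replace = TRUE)])
    # a slice of prescriptions comes from unmappable products
    if (length(products$unmapped)) {
      un <- runif(n_rx) < 0.05
      drug[un] <- sample(products$unmapped, sum(un), replace = TRUE)
    }
    st <- s0 + sample.int(span, n_rx, replace = TRUE) - 1L
    dur <- 1L + rpois(n_rx, 2)
    en <- pmin(st + dur - 1L, s1)
    # keep some exposures in the follow-up window so most patients pass the
    # post-discharge data requirement
    if (runif(1) < 0.9) {
      fday <- as.integer(eps$discharge_date[e]) + sample(1:7, 1L)
      st <- c(st, fday); en <- c(en, fday)
      drug <- c(drug, products$singles$drug_code[sample.int(n_single, 1L)])
    }
    out[[length(out) + 1L]] <- data.table(
      person_id = pid, drug_code = drug,
      start_date = as.Date(st, origin = "1970-01-01"),
      end_date = as.Date(en, origin = "1970-01-01"))
  }
  if (!length(out)) {
    return(data.table(person_id = character(), drug_code = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character())))
  }
  rbindlist(out)
}

# run the counting stages on a generated bundle and return per-patient
# realized categories (retention under the default eligibility policy)
.realized_categories <- function(bundle, followup_days = 7L) {
  adm <- extract_admissions(bundle$visit_occurrence)
  eps <- attach_followup(merge_admissions(adm), followup_days)
  elig <- eligibility_filter(eps, bundle$drug_exposure)
  eps <- eps[person_id %in% elig[keep == TRUE, person_id]]
  mp <- map_exposures(as.data.table(bundle$drug_exposure)[
    person_id %in% unique(eps$person_id)],
    suppressWarnings(load_dictionary(bundle$dictionary)))
  assign_cohort(mp$exposures, eps)$category
}

#' Calibrate stochastic prescribing intensities to a target level mix
#'
#' The mapping from a daily prescribing intensity to a realized
#' polypharmacy category is stochastic: a patient prescribed at a rate
#' aimed at 5-9 concurrent ingredients sometimes realizes 10 or more. To
#' hit a target category mix, this routine simulates small cohorts at each
#' intensity on a grid, estimates the intensity -> category confusion
#' matrix M, and solves the non-negative least-squares problem
#' `min || t(M) w - level_mix ||` with `sum(w) = 1` for mixture weights
#' over the grid. Sampling per-patient intensities from the calibrated
#' weights then yields realized category proportions matching the target
#' in expectation.
#'
#' @param config A [generator_config()] supplying `level_mix` and the
#'   cohort shape parameters.
#' @param grid Intensity grid (new prescriptions per observation day).
#' @param n_per_level Simulated patients per grid point.
#' @return List: `grid`, `weights` (summing to 1), `confusion` (grid x
#'   category matrix of realized proportions).
#' @export
calibrate_intensities <- function(config,
                                  grid = c(0.1, 0.25, 0.5, 0.9, 1.5,
                                           2.4, 3.6, 5.2, 7.5),
                                  n_per_level = 500L) {
  M <- matrix(0, length(grid), 4L,
              dimnames = list(NULL, .polypharmacy_levels))
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$n_patients <- as.integer(n_per_level)
    cfg$daily_rx_intensity[] <- grid[i]
    cfg$level_mix[] <- c(1, 0, 0, 0)  # single intensity class
    cfg$seed <- config$seed + i
    g <- generate_cohort(cfg, "stochastic")
    cats <- .realized_categories(g$bundle)
    M[i, ] <- as.numeric(table(cats)[.polypharmacy_levels]) / length(cats)
  }
  M[is.na(M)] <- 0
  target <- as.numeric(config$level_mix[.polypharmacy_levels])
  # augmented row enforces sum(w) ~= 1 inside the NNLS solve
  A <- rbind(t(M), rep(10, length(grid)))
  b <- c(target, 10)
  w <- pracma::lsqnonneg(A, b)$x
  w <- w / sum(w)
  list(grid = grid, weights = w, confusion = M)
}
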