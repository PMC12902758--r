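test_that("generator configuration is validated", {
  expect_error(generator_config(level_mix = c(nonpolypharmacy = 0.5,
                                              polypharmacy = 0.2,
                                              `major polypharmacy` = 0.2,
                                              `excessive polypharmacy` = 0.2)),
               "sum to 1")
  expect_error(generator_config(frac_unmapped_drugs = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(n_patients = -1), "non-negative")
})

test_that("the same seed reproduces a byte-identical bundle in both modes", {
  for (mode in c("constructive", "stochastic")) {
    g1 <- generate_cohort(generator_config(n_patients = 25, seed = 7), mode)
    g2 <- generate_cohort(generator_config(n_patients = 25, seed = 7), mode)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    write_bundle(g1$bundle, d1); write_bundle(g2$bundle, d2)
    for (f in list.files(d1)) {
      expect_identical(readLines(file.path(d1, f)),
                       readLines(file.path(d2, f)))
    }
  }
})

test_that("zero patients yield an empty bundle and empty ground truth", {
  g <- generate_cohort(generator_config(n_patients = 0, seed = 1))
  expect_equal(nrow(g$bundle$person), 0L)
  expect_equal(nrow(g$bundle$visit_occurrence), 0L)
  expect_equal(nrow(g$truth), 0L)
})

test_that("planted profiles attain the target count exactly once", {
  set.seed(88)
  dict <- suppressWarnings(load_dictionary(synthetic_dictionary()))
  per_prod <- dict[, .(k = .N), by = drug_code]
  products <- list(singles = per_prod[k == 1L], combos = per_prod[k > 1L],
                   unmapped = character())
  eps <- data.table(person_id = "p1",
                    admit_date = as.Date("2015-02-01"),
                    discharge_date = as.Date("2015-02-20"))
  for (target in c(2L, 5L, 12L, 20L)) {
    expo <- plant_profile(copy(eps), target, as.Date("2015-02-10"), products)
    mp <- map_exposures(expo, dict)
    epsf <- mk_episodes("p1", "2015-02-01", "2015-02-20")
    counts <- oracle_daily(mp$exposures, epsf)
    expect_equal(max(counts$n_ingredients), target)
    expect_equal(counts[n_ingredients == target, date], as.Date("2015-02-10"))
    expect_true(all(counts[date != as.Date("2015-02-10"),
                           n_ingredients] < target))
  }
  # target 1: a single one-day exposure in the follow-up window
  one <- plant_profile(copy(eps), 1L, as.Date("2015-02-23"), products)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start_date, one$end_date)
  # planted category at the top boundary
  expect_equal(as.character(categorize(20L)), "excessive polypharmacy")
  expect_equal(as.character(categorize(12L)), "major polypharmacy")
})

test_that("uniform gaps on 1..60 merge about half of consecutive admission pairs", {
  cfg <- generator_config(n_patients = 400, seed = 21, admissions_lambda = 1.5)
  g <- generate_cohort(cfg, "stochastic")
  adm <- extract_admissions(g$bundle$visit_occurrence)
  # recompute the expected merge fraction from the sampled gaps themselves
  gaps <- adm[, if (.N > 1L) .(gap = as.integer(admit_date[-1L] -
                                                  discharge_date[-.N])),
              by = person_id]$gap
  expected_frac <- mean(gaps <= 30)
  merged <- merge_admissions(adm)
  n_merges <- nrow(adm) - nrow(merged)
  observed_frac <- n_merges / length(gaps)
  expect_equal(observed_frac, expected_frac, tolerance = 0.02)
  # sanity: the configured distribution straddles 30, so the fraction is
  # near one half
  expect_gt(expected_frac, 0.35)
  expect_lt(expected_frac, 0.65)
})

test_that("doubling prescribing intensity increases mean maximum daily counts", {
  base <- generator_config(n_patients = 200, seed = 31,
                           level_mix = c(nonpolypharmacy = 0,
                                         polypharmacy = 1,
                                         `major polypharmacy` = 0,
                                         `excessive polypharmacy` = 0))
  hi <- base
  hi$daily_rx_intensity <- base$daily_rx_intensity * 2
  mean_max <- function(cfg) {
    g <- generate_cohort(cfg, "stochastic")
    eps <- attach_followup(merge_admissions(extract_admissions(
      g$bundle$visit_occurrence)))
    mp <- map_exposures(g$bundle$drug_exposure,
                        suppressWarnings(load_dictionary(g$bundle$dictionary)))
    mean(assign_cohort(mp$exposures, eps)$max_count)
  }
  expect_gt(mean_max(hi), mean_max(base))
})

test_that("a dictionary with no codeless products reports zero unmapped", {
  cfg <- generator_config(n_patients = 30, seed = 13, frac_unmapped_drugs = 0)
  g <- generate_cohort(cfg, "stochastic")
  mp <- map_exposures(g$bundle$drug_exposure,
                      suppressWarnings(load_dictionary(g$bundle$dictionary)))
  expect_equal(mp$report$n_unmapped, 0L)
})

test_that("calibrated intensities recover the target level mix at n = 2000", {
  cfg <- generator_config(n_patients = 2000, seed = 5)
  cal <- calibrate_intensities(cfg)
  # the calibrated mixture reproduces the target exactly in expectation
  fitted <- as.numeric(t(cal$confusion) %*% cal$weights)
  expect_equal(fitted, as.numeric(cfg$level_mix), tolerance = 0.01)
  g <- generate_cohort(cfg, "stochastic", calibration = cal)
  eps <- attach_followup(merge_admissions(extract_admissions(
    g$bundle$visit_occurrence)))
  elig <- eligibility_filter(eps, g$bundle$drug_exposure)
  eps <- eps[person_id %in% elig[keep == TRUE, person_id]]
  mp <- map_exposures(g$bundle$drug_exposure,
                      suppressWarnings(load_dictionary(g$bundle$dictionary)))
  cats <- assign_cohort(mp$exposures, eps)$category
  obs <- as.numeric(table(cats)[names(cfg$level_mix)]) / length(cats)
  tgt <- as.numeric(cfg$level_mix)
  se <- sqrt(tgt * (1 - tgt) / length(cats))
  expect_true(all(abs(obs - tgt) <= 3 * se))
})
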