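test_that("daily counts follow interval arithmetic with per-day distinctness", {
  eps <- mk_episodes("p1", "2015-01-01", "2015-01-20")
  d <- as.Date("2015-01-01")
  ann <- mk_annotated("p1", c("IA", "IB", "IC"),
                      c(d, d + 1, d + 1), c(d + 2, d + 3, d + 1))
  counts <- daily_counts(ann, eps)
  expect_equal(counts$n_ingredients, c(1L, 3L, 2L, 1L))
  expect_equal(counts$date, d + 0:3)
  # two products sharing an ingredient on a day count once
  dup <- rbind(ann, mk_annotated("p1", "IA", d, d))
  expect_equal(daily_counts(dup, eps)$n_ingredients, c(1L, 3L, 2L, 1L))
})

test_that("exposure days outside the observation period are clipped out", {
  eps <- mk_episodes("p1", "2015-01-10", "2015-01-12")
  ann <- mk_annotated("p1", "IA", "2015-01-05", "2015-01-25")
  counts <- daily_counts(ann, eps)
  # stay 3 days + 7 follow-up days = 10 observation days
  expect_equal(nrow(counts), 10L)
  expect_equal(range(counts$date),
               as.Date(c("2015-01-10", "2015-01-19")))
})

test_that("daily counts and max-day selection match the brute-force oracle", {
  set.seed(55)
  for (rep in 1:60) {
    rp <- rand_patient("p1", n_exposures = sample(10:50, 1))
    counts <- daily_counts(rp$annotated, rp$episodes)
    expect_equal(as.data.frame(counts),
                 as.data.frame(oracle_daily(rp$annotated, rp$episodes)),
                 ignore_attr = TRUE)
    got <- select_max_day(counts, rp$episodes)
    expect_equal(as.data.frame(got),
                 as.data.frame(oracle_max_day(counts, rp$episodes)),
                 ignore_attr = TRUE)
  }
})

test_that("max-day ties resolve to the day closest to its episode's admission", {
  # max on day 5 and day 9 of a stay starting day 3: day 5 wins (2 < 6)
  eps <- mk_episodes("p1", "2015-01-03", "2015-01-20")
  ann <- mk_annotated("p1",
                      c("I1", "I2", "I1", "I2"),
                      as.Date(c("2015-01-05", "2015-01-05",
                                "2015-01-09", "2015-01-09")))
  got <- select_max_day(daily_counts(ann, eps), eps)
  expect_equal(got$max_count, 2L)
  expect_equal(got$max_date, as.Date("2015-01-05"))
})

test_that("tie-break distance is episode-local, not distance to first admission", {
  # episode 1: Jan 1-10; episode 2: Mar 1-10. Max attained on Jan 5
  # (offset 4 in episode 1) and Mar 2 (offset 1 in episode 2):
  # the episode-2 date wins despite being later in calendar time.
  eps <- mk_episodes("p1", c("2015-01-01", "2015-03-01"),
                     c("2015-01-10", "2015-03-10"))
  ann <- mk_annotated("p1", c("I1", "I2", "I1", "I2"),
                      as.Date(c("2015-01-05", "2015-01-05",
                                "2015-03-02", "2015-03-02")))
  got <- select_max_day(daily_counts(ann, eps), eps)
  expect_equal(got$max_date, as.Date("2015-03-02"))
})

test_that("category boundaries sit exactly at 5, 10, and 20", {
  expect_equal(as.character(categorize(c(0, 4, 5, 9, 10, 19, 20, 100))),
               c("nonpolypharmacy", "nonpolypharmacy",
                 "polypharmacy", "polypharmacy",
                 "major polypharmacy", "major polypharmacy",
                 "excessive polypharmacy", "excessive polypharmacy"))
  expect_true(is.ordered(categorize(0:25)))
  expect_true(all(diff(as.integer(categorize(0:25))) >= 0))
  expect_equal(which(diff(as.integer(categorize(0:25))) == 1L), c(5, 10, 20))
  expect_error(categorize(-1), "non-negative")
})

test_that("adding an exposure never decreases any day's count", {
  set.seed(66)
  for (rep in 1:20) {
    rp <- rand_patient("p1", n_exposures = 15)
    base <- daily_counts(rp$annotated, rp$episodes)
    extra <- mk_annotated("p1", "IZZ",
                          rp$episodes$admit_date + sample(0:5, 1),
                          rp$episodes$admit_date + sample(6:12, 1))
    more <- daily_counts(rbind(rp$annotated, extra), rp$episodes)
    j <- merge(base, more, by = c("person_id", "date"), all.x = TRUE)
    expect_true(all(j$n_ingredients.y >= j$n_ingredients.x))
  }
})

test_that("max count is invariant to splitting an exposure into sub-intervals", {
  eps <- mk_episodes("p1", "2015-01-01", "2015-01-20")
  whole <- mk_annotated("p1", "IA", "2015-01-02", "2015-01-10")
  split <- mk_annotated("p1", c("IA", "IA"),
                        c("2015-01-02", "2015-01-06"),
                        c("2015-01-05", "2015-01-10"))
  other <- mk_annotated("p1", "IB", "2015-01-04", "2015-01-04")
  a <- select_max_day(daily_counts(rbind(whole, other), eps), eps)
  b <- select_max_day(daily_counts(rbind(split, other), eps), eps)
  expect_equal(a, b)
})

test_that("cohort assignment is deterministic and order-invariant", {
  g <- generate_cohort(generator_config(n_patients = 40, seed = 9))
  eps <- attach_followup(merge_admissions(extract_admissions(g$bundle$visit_occurrence)))
  mp <- map_exposures(g$bundle$drug_exposure,
                      suppressWarnings(load_dictionary(g$bundle$dictionary)))
  a1 <- assign_cohort(mp$exposures, eps)
  perm <- mp$exposures[sample(.N)]
  a2 <- assign_cohort(perm, eps)
  expect_equal(as.data.frame(a1), as.data.frame(a2), ignore_attr = TRUE)
})

test_that("patients with no mapped exposures get count zero, nonpolypharmacy", {
  eps <- mk_episodes("p1", "2015-01-01", "2015-01-10")
  ann <- mk_annotated(character(), character(), as.Date(character()))
  a <- assign_cohort(ann, eps)
  expect_equal(a$max_count, 0L)
  expect_true(is.na(a$max_date))
  expect_equal(as.character(a$category), "nonpolypharmacy")
})
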