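test_that("age and stratum computation follow year arithmetic", {
  expect_equal(compute_age(1950, as.Date("2015-06-01")), 65L)
  expect_equal(compute_age(1952, as.Date("2015-06-01")), 63L)
  expect_equal(compute_age(1930, as.Date("2015-06-01")), 85L)
  expect_equal(as.character(age_stratum(c(65, 63, 85, 72))),
               c("60-69", "60-69", ">=80", "70-79"))
  expect_true(is.na(age_stratum(45)))
})

test_that("persons with missing year_of_birth are excluded with a warning", {
  person <- data.table(person_id = c("p1", "p2"),
                       year_of_birth = c(1940L, NA),
                       gender = "female")
  eps <- mk_episodes(c("p1", "p2"), "2015-01-01", "2015-01-10")
  expect_warning(ages <- cohort_ages(person, eps), "missing year_of_birth")
  expect_equal(ages$person_id, "p1")
  expect_equal(ages$age, 75L)
})

# a small cohort built by hand: 3 patients >= 65, 1 below the floor
pattern_fixture <- function() {
  person <- data.table(person_id = c("p1", "p2", "p3", "p4"),
                       year_of_birth = c(1940L, 1945L, 1930L, 1980L),
                       gender = "female")
  eps <- mk_episodes(c("p1", "p2", "p3", "p4"),
                     "2015-01-01", "2015-01-10")
  d <- as.Date("2015-01-02")
  ann <- rbind(
    mk_annotated("p1", c("I1", "I2", "I3"), d, d + 3,
                 atc2 = c("J01", "N02", "A02")),
    mk_annotated("p1", "I9", d + 8, d + 8, atc2 = "C01"),  # off the max day
    mk_annotated("p2", c("I4", "I5"), d, d, atc2 = c("J01", "J01")),
    mk_annotated("p3", "I6", d, d + 1, atc2 = "N02"),
    mk_annotated("p4", c("I7", "I8"), d, d, atc2 = c("J01", "N02")))
  list(person = person, episodes = eps, annotated = ann)
}

test_that("single frequencies count each patient at most once per class", {
  fx <- pattern_fixture()
  asg <- assign_cohort(fx$annotated, fx$episodes)
  ages <- cohort_ages(fx$person, fx$episodes)
  sf <- single_frequencies(fx$annotated, asg, ages, fx$episodes)
  # p4 (age 35) is excluded; p1 and p2 both use J01 once each
  expect_equal(sf[atc2 == "J01", sum(n_patients)], 2L)
  # p2's two J01 products on one day still count that patient once
  expect_equal(sf[atc2 == "J01" & category == "nonpolypharmacy", n_patients], 2L)
  expect_false("I7" %in% sf$atc2)
})

test_that("single frequencies equal a membership-matrix enumeration on a cohort", {
  g <- generate_cohort(generator_config(n_patients = 30, seed = 23))
  eps <- attach_followup(merge_admissions(extract_admissions(
    g$bundle$visit_occurrence)))
  mp <- map_exposures(g$bundle$drug_exposure,
                      suppressWarnings(load_dictionary(g$bundle$dictionary)))
  excl <- exclude_atc2(mp$exposures)
  asg <- assign_cohort(excl, eps)
  ages <- cohort_ages(g$bundle$person, eps)
  sf <- single_frequencies(excl, asg, ages, eps)
  # brute force: patient x class membership from clipped exposures
  pop <- ages[age >= 65, person_id]
  memb <- unique(clip_to_observation(excl, eps)[person_id %in% pop,
                                                .(person_id, atc2)])
  memb <- merge(memb, asg[, .(person_id, category)], by = "person_id")
  brute <- memb[, .(n_patients = .N), by = .(category, atc2)]
  m <- merge(sf, brute, by = c("category", "atc2"), all = TRUE)
  expect_true(all(m$n_patients.x == m$n_patients.y))
})

test_that("combination keys are sorted, deduplicated class sets of the max day", {
  fx <- pattern_fixture()
  asg <- assign_cohort(fx$annotated, fx$episodes)
  ages <- cohort_ages(fx$person, fx$episodes)
  cp <- combination_patterns(fx$annotated, asg, ages, fx$episodes)
  expect_equal(cp[n_patients == 1 & grepl("J01", combo_key), combo_key],
               c("A02|J01|N02", "J01"))
  # p2: two J01 ingredients -> singleton key after dedup
  expect_true("J01" %in% cp$combo_key)
  # one key per contributing patient
  expect_equal(sum(cp$n_patients), 3L)
})

test_that("combination counts match direct enumeration on a generated cohort", {
  g <- generate_cohort(generator_config(n_patients = 50, seed = 29))
  eps <- attach_followup(merge_admissions(extract_admissions(
    g$bundle$visit_occurrence)))
  mp <- map_exposures(g$bundle$drug_exposure,
                      suppressWarnings(load_dictionary(g$bundle$dictionary)))
  excl <- exclude_atc2(mp$exposures)
  asg <- assign_cohort(excl, eps)
  ages <- cohort_ages(g$bundle$person, eps)
  cp <- combination_patterns(excl, asg, ages, eps)
  pop <- asg[ages[age >= 65], on = "person_id", nomatch = NULL][max_count >= 1]
  brute <- list()
  clipped <- clip_to_observation(excl, eps)
  for (i in seq_len(nrow(pop))) {
    pid <- pop$person_id[i]; md <- pop$max_date[i]
    cls <- sort(unique(clipped[person_id == pid & start_date <= md &
                                 end_date >= md, atc2]))
    brute[[i]] <- data.table(category = pop$category[i],
                             combo_key = paste(cls, collapse = "|"))
  }
  brute <- rbindlist(brute)[, .(n_patients = .N), by = .(category, combo_key)]
  m <- merge(cp, brute, by = c("category", "combo_key"), all = TRUE)
  expect_true(all(m$n_patients.x == m$n_patients.y))
  # conservation: one contribution per patient with a positive count
  expect_equal(sum(cp$n_patients), nrow(pop))
})

test_that("top-N ranking sorts by count with lexicographic tie-break", {
  rows <- data.table(category = "polypharmacy",
                     atc2 = c("N02", "A02", "J01", "C01"),
                     n_patients = c(5L, 3L, 3L, 1L))
  top <- top_patterns(rows, n = 3)
  expect_equal(top$atc2, c("N02", "A02", "J01"))
  expect_equal(top$rank, 1:3)
  # n larger than row count returns everything
  expect_equal(nrow(top_patterns(rows, n = 10)), 4L)
})

test_that("removing excluded-class rows never changes other pattern counts", {
  g <- generate_cohort(generator_config(n_patients = 40, seed = 37))
  eps <- attach_followup(merge_admissions(extract_admissions(
    g$bundle$visit_occurrence)))
  mp <- map_exposures(g$bundle$drug_exposure,
                      suppressWarnings(load_dictionary(g$bundle$dictionary)))
  excl <- exclude_atc2(mp$exposures)
  asg <- assign_cohort(excl, eps)
  ages <- cohort_ages(g$bundle$person, eps)
  sf1 <- single_frequencies(excl, asg, ages, eps)
  # feeding already-filtered input again is a no-op
  sf2 <- single_frequencies(exclude_atc2(excl), asg, ages, eps)
  expect_equal(as.data.frame(sf1), as.data.frame(sf2), ignore_attr = TRUE)
  expect_false("B05" %in% sf1$atc2)
})
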