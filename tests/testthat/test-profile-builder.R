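test_that("day offsets and ages follow exact calendar arithmetic", {
  expect_identical(day_offset("2020-01-01", "2020-01-01"), 0L)
  expect_identical(day_offset("2019-10-22", "2020-01-01"), -71L)
  expect_identical(day_offset("2020-01-26", "2020-01-01"), 25L)

  expect_identical(age_at("2018-03-10", "1972-03-10"), 46L)  # exact birthday
  expect_identical(age_at("2018-03-09", "1972-03-10"), 45L)  # day before
  expect_identical(age_at("2000-07-01", "2000-07-01"), 0L)
  expect_error(age_at("2000-06-30", "2000-07-01"), "birth_date after")
})

test_that("measurement classification respects inclusive reference ranges", {
  expect_identical(classify_measurement(15.2, 4, 11), "abnormal_high")
  expect_identical(classify_measurement(11, 4, 11), "normal")
  expect_identical(classify_measurement(4, 4, 11), "normal")
  expect_identical(classify_measurement(3.2, 4, 11), "abnormal_low")
  expect_identical(classify_measurement(7, NA, NA), "unknown")
  expect_identical(classify_measurement(NA, 4, 11), "unknown")
  # one-sided ranges classify against the available bound
  expect_identical(classify_measurement(12, NA, 11), "abnormal_high")
  expect_identical(classify_measurement(7, NA, 11), "normal")
  expect_identical(classify_measurement(2, 4, NA), "abnormal_low")
  expect_error(classify_measurement(5, 11, 4), "exceeds")
})

test_that("day formatting dashes runs of four and slashes the rest", {
  expect_identical(format_days(1:5), "day 1-5")
  expect_identical(format_days(c(0L, 1L, 2L, 5L)), "day 0/1/2/5")
  expect_identical(format_days(3L), "day 3")
  expect_identical(format_days(c(-1L, 0L)), "day -1/0")
  expect_identical(format_days(c(-5L, -4L, -3L, -2L, 7L)), "day -5--2/7")
  expect_error(format_days(integer()), "empty")
  # parse of its own output is the identity on the day set
  set.seed(4)
  for (i in 1:50) {
    days <- sort(sample(-30:30, sample(1:12, 1)))
    expect_identical(parse_days(format_days(days)), as.integer(days))
  }
})

drug_rows <- function(concept_id, start, days_supply = NA_integer_,
                      end = NA_character_) {
  data.frame(person_id = 1L, domain = "drug", concept_id = concept_id,
             start_date = as.Date(start),
             end_date = as.Date(end),
             value_as_number = NA_real_, range_low = NA_real_,
             range_high = NA_real_, unit = NA_character_,
             days_supply = days_supply, visit_id = NA_integer_)
}

test_that("drug summaries roll up to ingredients and union day intervals", {
  v <- toy_vocab()
  idx <- as.Date("2020-01-01")
  one <- summarize_drugs(drug_rows(2110L, "2020-01-01", 3L), v, idx)
  expect_identical(length(one), 1L)
  expect_identical(one[[1]]$concept_name, "metronidazole")
  expect_identical(one[[1]]$duration_days, 3L)
  expect_identical(one[[1]]$day_offsets, 0L)

  # overlapping refills: offsets [0,2] and [1,4] cover {0..4} -> 5 days
  two <- summarize_drugs(rbind(
    drug_rows(2110L, "2020-01-01", 3L),
    drug_rows(2110L, "2020-01-02", 4L)), v, idx)
  expect_identical(length(two), 1L)
  expect_identical(two[[1]]$duration_days, 5L)
  expect_identical(two[[1]]$day_offsets, c(0L, 1L))

  # distinct ingredients never pool
  sep <- summarize_drugs(rbind(
    drug_rows(2110L, "2020-01-01", 3L),
    drug_rows(2210L, "2020-01-01", 5L)), v, idx)
  expect_identical(length(sep), 2L)
  expect_setequal(vapply(sep, `[[`, character(1), "concept_name"),
                  c("metronidazole", "ceftriaxone"))

  # span fallback when days_supply is absent; single day when both absent
  span <- summarize_drugs(drug_rows(2110L, "2020-01-01",
                                    end = "2020-01-05"), v, idx)
  expect_identical(span[[1]]$duration_days, 5L)
  point <- summarize_drugs(drug_rows(2110L, "2020-01-03"), v, idx)
  expect_identical(point[[1]]$duration_days, 1L)
})

meas_rows <- function(concept_id, dates, value, lo = 4, hi = 11) {
  data.frame(person_id = 1L, domain = "measurement",
             concept_id = concept_id, start_date = as.Date(dates),
             end_date = as.Date(NA),
             value_as_number = value, range_low = lo, range_high = hi,
             unit = NA_character_, days_supply = NA_integer_,
             visit_id = NA_integer_)
}

test_that("event grouping splits on qualifier and collapses same-day codes", {
  v <- toy_vocab()
  idx <- as.Date("2020-01-01")
  normal <- group_events(meas_rows(4100L, idx + c(3, 4, 6, 7), 8), idx, v)
  expect_identical(length(normal), 1L)
  expect_identical(normal[[1]]$qualifier, "normal")
  expect_identical(normal[[1]]$day_offsets, c(3L, 4L, 6L, 7L))

  split_q <- group_events(rbind(
    meas_rows(4100L, idx + 1, 15),
    meas_rows(4100L, idx + 3, 8)), idx, v)
  expect_identical(length(split_q), 2L)
  expect_setequal(vapply(split_q, `[[`, character(1), "qualifier"),
                  c("abnormal_high", "normal"))

  cond <- data.frame(person_id = 1L, domain = "condition",
                     concept_id = 1200L, start_date = rep(idx, 2),
                     end_date = as.Date(NA), value_as_number = NA_real_,
                     range_low = NA_real_, range_high = NA_real_,
                     unit = NA_character_, days_supply = NA_integer_,
                     visit_id = NA_integer_)
  dedup <- group_events(cond, idx, v)
  expect_identical(length(dedup), 1L)
  expect_identical(dedup[[1]]$day_offsets, 0L)
  expect_identical(dedup[[1]]$qualifier, "none")
})

test_that("index-visit summaries order and annotate stays", {
  idx <- as.Date("2020-01-01")
  visits <- data.frame(
    visit_id = 1:2, person_id = 1L,
    visit_kind = c("emergency room", "inpatient"),
    start_date = c(idx, idx), end_date = c(idx, idx + 3))
  expect_identical(summarize_index_visit(visits, idx),
                   "emergency room followed by hospitalization (3 days)")
  single <- data.frame(visit_id = 1L, person_id = 1L,
                       visit_kind = "inpatient",
                       start_date = idx, end_date = idx + 7)
  expect_identical(summarize_index_visit(single, idx),
                   "hospitalization (7 days)")
  off <- data.frame(visit_id = 1L, person_id = 1L,
                    visit_kind = "outpatient",
                    start_date = idx + 30, end_date = idx + 30)
  expect_identical(summarize_index_visit(off, idx), "none recorded")
  expect_identical(summarize_index_visit(off[0, ], idx), "none recorded")
})

test_that("profiles place planted facts in their sections and only there", {
  g <- generate_cdm(1, case_prevalence = 1, capture_probability = 1,
                    noise_rate = 0, seed = 3)
  v <- toy_vocab()
  cfg <- toy_phenotype_config(v)
  store <- load_cdm(g$directory, quiet = TRUE)
  cohort <- read_cohort(file.path(g$directory, "cohort.csv"))
  p <- build_profile(cohort[1, ], cfg, store, v)
  section_names <- function(el) vapply(p$sections[[el]], `[[`, character(1),
                                       "concept_name")
  expect_true("abdominal pain" %in% section_names("presentation"))
  expect_true("computed tomography of abdomen" %in%
                section_names("diagnostic_procedures"))
  expect_true("leukocytes" %in% section_names("lab_tests"))
  expect_true("metronidazole" %in% section_names("medications"))
  expect_true("appendectomy" %in% section_names("treatment_procedures"))
})

test_that("irrelevant patients yield demographics-only profiles", {
  idx <- as.Date("2020-01-01")
  dir <- write_cdm_fixture(list(
    person = data.frame(person_id = 1L, birth_datetime = "1980-01-01",
                        gender = "female", race = "white",
                        ethnicity = "not hispanic"),
    condition_occurrence = data.frame(
      person_id = 1L, condition_concept_id = 9100L,  # outside all sets
      condition_start_date = as.character(idx), condition_end_date = "")))
  v <- toy_vocab()
  cfg <- toy_phenotype_config(v)
  store <- load_cdm(dir, quiet = TRUE)
  p <- build_profile(list(person_id = 1L, index_date = idx), cfg, store, v)
  expect_identical(p$age_years, 40L)
  expect_true(all(lengths(p$sections) == 0L))
  expect_identical(p$visit_summary, "none recorded")
})

test_that("window exclusion keeps day -1 events out of presentation", {
  idx <- as.Date("2020-01-01")
  dir <- write_cdm_fixture(list(
    person = data.frame(person_id = 1L, birth_datetime = "1980-01-01",
                        gender = "female", race = "white",
                        ethnicity = "not hispanic"),
    condition_occurrence = data.frame(
      person_id = 1L, condition_concept_id = 1200L,
      condition_start_date = as.character(idx - 1), condition_end_date = "")))
  v <- toy_vocab()
  cfg <- toy_phenotype_config(v)
  p <- build_profile(list(person_id = 1L, index_date = idx), cfg,
                     load_cdm(dir, quiet = TRUE), v)
  expect_identical(length(p$sections$presentation), 0L)
  expect_identical(
    vapply(p$sections$prior_history, `[[`, character(1), "concept_name"),
    "abdominal pain")
})

test_that("batches are blinded bijectively and deterministic per seed", {
  g <- generate_cdm(20, seed = 13, noise_rate = 2)
  v <- toy_vocab()
  cfg <- toy_phenotype_config(v)
  store <- load_cdm(g$directory, quiet = TRUE)
  cohort <- read_cohort(file.path(g$directory, "cohort.csv"))

  b1 <- build_batch(cohort, cfg, store, v, seed = 7)
  expect_identical(length(b1$profiles), 20L)
  expect_identical(sort(b1$blinding_map$person_id), cohort$person_id)
  expect_identical(anyDuplicated(b1$blinding_map$study_id), 0L)

  b2 <- build_batch(cohort, cfg, store, v, seed = 7)
  json1 <- vapply(b1$profiles, render_profile, character(1),
                  options = render_options("json"))
  json2 <- vapply(b2$profiles, render_profile, character(1),
                  options = render_options("json"))
  expect_identical(json1, json2)

  b3 <- build_batch(cohort, cfg, store, v, seed = 8)
  expect_false(identical(b1$blinding_map, b3$blinding_map))
  # same profile contents under either seed, matched through person ids
  by_person <- function(b) {
    m <- b$blinding_map
    prof <- b$profiles[match(m$study_id[order(m$person_id)],
                             vapply(b$profiles, `[[`, character(1),
                                    "study_id"))]
    lapply(prof, function(p) { p$study_id <- ""; p })
  }
  expect_equal(by_person(b1), by_person(b3))

  expect_error(build_batch(rbind(cohort, cohort[1, ]), cfg, store, v, 1),
               "duplicate person_id")
})

test_that("noise concepts never leak into profiles and sections re-verify", {
  g <- generate_cdm(30, seed = 21, noise_rate = 12)
  v <- toy_vocab()
  cfg <- toy_phenotype_config(v)
  store <- load_cdm(g$directory, quiet = TRUE)
  cohort <- read_cohort(file.path(g$directory, "cohort.csv"))
  noise_names <- tolower(
    v$concepts$concept_name[v$concepts$concept_id >= 9000L])
  spec_by_element <- split(cfg$specs,
                           vapply(cfg$specs, `[[`, character(1), "element"))
  for (i in seq_len(nrow(cohort))) {
    p <- build_profile(cohort[i, ], cfg, store, v)
    for (el in names(p$sections)) {
      for (s in p$sections[[el]]) {
        expect_false(s$concept_name %in% noise_names)
        # independent brute-force re-verification of window membership
        specs <- spec_by_element[[el]]
        backed <- any(vapply(specs, function(spec) {
          ev <- brute_force_events(store, cohort$person_id[i], spec,
                                   cohort$index_date[i])
          if (!nrow(ev)) return(FALSE)
          ids <- ev$concept_id
          if (el == "medications") {
            ids <- vapply(ids, function(id) {
              ing <- ingredient_of(id, v)
              if (is.na(ing)) id else ing
            }, integer(1))
          }
          s$concept_id %in% ids
        }, logical(1)))
        expect_true(backed)
      }
    }
  }
})
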