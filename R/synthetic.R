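# Synthetic CDM fixtures with known ground truth: a toy vocabulary, patients
# with planted phenotype signatures plus background noise, and simulated
# reviewers. Everything is reproducible per seed so the whole pipeline is
# testable offline.

#' A fixed toy vocabulary with hierarchy, ingredients and reference ranges
#'
#' A small versioned stand-in (synthetic, not a reconstruction of any real
#' code list) shaped like the vocabularies a profile needs: a three-level
#' condition hierarchy (a "disorder of abdomen" grouper over diseases,
#' symptoms and competitor diagnoses, with a subtype leaf), an esophageal
#' grouper for the competing-diagnosis signature, drug classes whose leaves
#' roll up to exactly one ingredient, diagnostic/treatment procedures,
#' measurements with canonical reference ranges, and background noise
#' concepts that belong to no signature set. Edge list is direct
#' parent-child; [vocabulary_index()] computes the transitive closure.
#'
#' @return List with `concepts` and `ancestry` data frames (byte-stable
#'   across runs) in the `concept.csv` / `concept_ancestor.csv` contracts.
#' @export
make_toy_vocabulary <- function() {
  concepts <- do.call(rbind, lapply(list(
    # condition hierarchy: grouper -> diseases/symptoms/competitors -> subtype
    list(1000L, "disorder of abdomen", "condition", "SNOMED", "Clinical Finding"),
    list(1100L, "acute appendicitis", "condition", "SNOMED", "Clinical Finding"),
    list(1110L, "acute gangrenous appendicitis", "condition", "SNOMED", "Clinical Finding"),
    list(1200L, "abdominal pain", "condition", "SNOMED", "Clinical Finding"),
    list(1210L, "nausea", "condition", "SNOMED", "Clinical Finding"),
    list(1220L, "vomiting", "condition", "SNOMED", "Clinical Finding"),
    list(1300L, "diverticulitis of colon", "condition", "SNOMED", "Clinical Finding"),
    list(1310L, "crohn's disease", "condition", "SNOMED", "Clinical Finding"),
    list(1320L, "umbilical hernia", "condition", "SNOMED", "Clinical Finding"),
    list(1400L, "acquired absence of organ", "condition", "SNOMED", "Clinical Finding"),
    list(1450L, "disorder of esophagus", "condition", "SNOMED", "Clinical Finding"),
    list(1500L, "esophagitis", "condition", "SNOMED", "Clinical Finding"),
    list(1505L, "barrett's esophagus", "condition", "SNOMED", "Clinical Finding"),
    list(1510L, "gastrointestinal hemorrhage", "condition", "SNOMED", "Clinical Finding"),
    list(1520L, "hematemesis", "condition", "SNOMED", "Clinical Finding"),
    # drugs: ATC-style classes over RxNorm-style ingredients and products
    list(2000L, "antiinfectives for systemic use", "drug", "ATC", "ATC 1st"),
    list(2100L, "metronidazole", "drug", "RxNorm", "Ingredient"),
    list(2110L, "metronidazole 500 mg oral tablet", "drug", "RxNorm", "Clinical Drug"),
    list(2200L, "ceftriaxone", "drug", "RxNorm", "Ingredient"),
    list(2210L, "ceftriaxone 1 g injection", "drug", "RxNorm", "Clinical Drug"),
    list(2300L, "drugs for acid related disorders", "drug", "ATC", "ATC 2nd"),
    list(2400L, "pantoprazole", "drug", "RxNorm", "Ingredient"),
    list(2410L, "pantoprazole 40 mg oral tablet", "drug", "RxNorm", "Clinical Drug"),
    list(2500L, "famotidine", "drug", "RxNorm", "Ingredient"),
    list(2510L, "famotidine 20 mg oral tablet", "drug", "RxNorm", "Clinical Drug"),
    list(2600L, "ondansetron", "drug", "RxNorm", "Ingredient"),
    list(2610L, "ondansetron 4 mg oral tablet", "drug", "RxNorm", "Clinical Drug"),
    # procedures
    list(3100L, "computed tomography of abdomen", "procedure", "CPT4", "CPT4"),
    list(3200L, "appendectomy", "procedure", "CPT4", "CPT4"),
    list(3300L, "esophagogastroduodenoscopy", "procedure", "CPT4", "CPT4"),
    list(3400L, "colectomy", "procedure", "CPT4", "CPT4"),
    # measurements (canonical reference ranges live in MEASUREMENT_RANGES)
    list(4100L, "leukocytes", "measurement", "LOINC", "Lab Test"),
    list(4200L, "neutrophils", "measurement", "LOINC", "Lab Test"),
    list(4300L, "neutrophils/100 leukocytes", "measurement", "LOINC", "Lab Test"),
    # observations
    list(5100L, "family history of acute appendicitis", "observation", "SNOMED", "Context-dependent"),
    # background noise concepts, outside every signature set
    list(9100L, "backache", "condition", "SNOMED", "Clinical Finding"),
    list(9110L, "cough", "condition", "SNOMED", "Clinical Finding"),
    list(9120L, "essential hypertension", "condition", "SNOMED", "Clinical Finding"),
    list(9200L, "lisinopril", "drug", "RxNorm", "Ingredient"),
    list(9210L, "lisinopril 10 mg oral tablet", "drug", "RxNorm", "Clinical Drug"),
    list(9300L, "plain chest x-ray", "procedure", "CPT4", "CPT4"),
    list(9400L, "hemoglobin", "measurement", "LOINC", "Lab Test"),
    list(9500L, "tobacco smoking status", "observation", "LOINC", "Survey")
  ), function(row) {
    data.frame(concept_id = row[[1]], concept_name = row[[2]],
               domain_id = row[[3]], vocabulary_id = row[[4]],
               concept_class_id = row[[5]])
  }))
  edges <- matrix(c(
    1000L, 1100L,
    1100L, 1110L,
    1000L, 1200L,
    1000L, 1210L,
    1000L, 1220L,
    1000L, 1300L,
    1000L, 1310L,
    1000L, 1320L,
    1450L, 1500L,
    1450L, 1505L,
    1450L, 1520L,
    2000L, 2100L,
    2100L, 2110L,
    2000L, 2200L,
    2200L, 2210L,
    2300L, 2400L,
    2400L, 2410L,
    2300L, 2500L,
    2500L, 2510L,
    2600L, 2610L,
    9200L, 9210L
  ), ncol = 2L, byrow = TRUE)
  ancestry <- data.frame(ancestor_concept_id = edges[, 1L],
                         descendant_concept_id = edges[, 2L])
  list(concepts = concepts, ancestry = ancestry)
}

# reference ranges used when emitting synthetic measurement rows
MEASUREMENT_RANGES <- list(
  `4100` = c(low = 4, high = 11),     # leukocytes, 10^9/L
  `4200` = c(low = 1.5, high = 7.5),  # neutrophils, 10^9/L
  `4300` = c(low = 40, high = 75),    # neutrophils/100 leukocytes, %
  `9400` = c(low = 12, high = 17)     # hemoglobin, g/dL
)

#' The toy phenotype definition used by the synthetic generator
#'
#' Binds the toy vocabulary's concept sets to conceptual elements for an
#' acute-abdominal-disease archetype: presentation and history draw on all
#' descendants of the abdominal-disorder grouper, competing diagnoses on the
#' inflammatory-bowel and esophageal sets, diagnostics/labs/treatment/
#' medications on the corresponding procedure, measurement and drug-class
#' sets, complications on the disease subtype.
#'
#' @param vocab A `keeper_vocabulary` built from [make_toy_vocabulary()].
#' @return A `keeper_config`.
#' @export
toy_phenotype_config <- function(vocab) {
  config_from_list(toy_config_list(), vocab, where = "toy config")
}

toy_config_list <- function() {
  seed <- function(id, desc = TRUE, excl = FALSE) {
    list(concept_id = id, include_descendants = desc, excluded = excl)
  }
  list(
    phenotype_name = "acute appendicitis (synthetic)",
    concept_sets = list(
      relevant_conditions = list(seed(1000L), seed(1450L),
                                 seed(1510L, desc = FALSE)),
      family_history = list(seed(5100L, desc = FALSE)),
      competing_conditions = list(seed(1300L), seed(1310L), seed(1450L),
                                  seed(1510L, desc = FALSE)),
      diagnostic_procedures = list(seed(3100L, desc = FALSE),
                                   seed(3300L, desc = FALSE)),
      lab_panel = list(seed(4100L, desc = FALSE), seed(4200L, desc = FALSE),
                       seed(4300L, desc = FALSE)),
      treatment_procedures = list(seed(3200L, desc = FALSE),
                                  seed(3400L, desc = FALSE)),
      relevant_drugs = list(seed(2000L), seed(2300L), seed(2600L)),
      complication_conditions = list(seed(1110L, desc = FALSE),
                                     seed(1400L, desc = FALSE))
    ),
    elements = list(
      list(element = "presentation", domains = list("condition"),
           concept_set = "relevant_conditions"),
      list(element = "prior_history", domains = list("condition"),
           concept_set = "relevant_conditions"),
      list(element = "comorbidities_risk_factors",
           domains = list("observation"), concept_set = "family_history"),
      list(element = "competing_diagnoses", domains = list("condition"),
           concept_set = "competing_conditions"),
      list(element = "diagnostic_procedures", domains = list("procedure"),
           concept_set = "diagnostic_procedures"),
      list(element = "lab_tests", domains = list("measurement"),
           concept_set = "lab_panel"),
      list(element = "treatment_procedures", domains = list("procedure"),
           concept_set = "treatment_procedures"),
      list(element = "medications", domains = list("drug"),
           concept_set = "relevant_drugs"),
      list(element = "complications", domains = list("condition"),
           concept_set = "complication_conditions")
    )
  )
}

#' Generate a synthetic CDM directory with known ground truth
#'
#' Each patient is drawn case with probability `case_prevalence`. Cases
#' receive the planted phenotype signature — index-day symptom and diagnosis
#' codes, a diagnostic procedure on day 0, abnormal-then-normalizing
#' leukocyte values over days 0-3, an antibiotic with days supply on day 0,
#' an appendectomy on day 2 and (with probability 1/2) a complication on day
#' 25 — while controls receive a competing-diagnosis signature (hematemesis
#' with a rule-out diagnosis code, endoscopy, normal labs, acid-suppressing
#' drugs and a subsequent esophagitis code). Every planted fact is kept with
#' probability `capture_probability`, emulating incomplete data capture.
#' Poisson(`noise_rate`) background events per patient are drawn from
#' concepts outside all configured concept sets. All tables are written as
#' the CSV dialect read by [load_cdm()], plus `cohort.csv`, `truth.csv` and
#' the toy `concept.csv` / `concept_ancestor.csv`. Output is fully
#' reproducible per seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param case_prevalence Probability a patient is a true case.
#' @param capture_probability Per-fact probability a planted fact is
#'   recorded.
#' @param noise_rate Expected background events per patient.
#' @param seed Integer RNG seed.
#' @param directory Output directory (created; default a fresh tempdir).
#' @return List with `directory`, `truth` (person_id, label), `manifest`
#'   (the planted facts actually recorded) and the generation parameters.
#' @export
generate_cdm <- function(n_patients, case_prevalence = 0.5,
                         capture_probability = 1, noise_rate = 5,
                         seed = 1L,
                         directory = tempfile("synthetic_cdm_")) {
  stopifnot(n_patients >= 1,
            case_prevalence >= 0, case_prevalence <= 1,
            capture_probability >= 0, capture_probability <= 1,
            noise_rate >= 0)
  out <- with_seed(seed, generate_cdm_impl(
    n_patients, case_prevalence, capture_probability, noise_rate))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  voc <- make_toy_vocabulary()
  write_one <- function(df, name) {
    utils::write.csv(df, file.path(directory, name), row.names = FALSE,
                     na = "")
  }
  write_one(voc$concepts, "concept.csv")
  write_one(voc$ancestry, "concept_ancestor.csv")
  for (nm in names(out$tables)) write_one(out$tables[[nm]], paste0(nm, ".csv"))
  write_one(out$cohort, "cohort.csv")
  write_one(out$truth, "truth.csv")
  list(directory = directory, truth = out$truth, manifest = out$manifest,
       n_patients = n_patients, case_prevalence = case_prevalence,
       capture_probability = capture_probability, noise_rate = noise_rate,
       seed = as.integer(seed))
}

generate_cdm_impl <- function(n_patients, prevalence, capture, noise_rate) {
  persons <- conditions <- drugs <- procedures <- measurements <-
    observations <- visits <- manifest <- list()
  labels <- character(n_patients)
  visit_id <- 0L

  noise_pool <- data.frame(
    domain = c("condition", "condition", "condition", "drug", "procedure",
               "measurement", "observation"),
    concept_id = c(9100L, 9110L, 9120L, 9210L, 9300L, 9400L, 9500L))

  for (pid in seq_len(n_patients)) {
    birth <- as.Date("1940-01-01") +
      sample.int(as.integer(as.Date("2004-12-31") - as.Date("1940-01-01")), 1L)
    index <- as.Date("2018-01-01") +
      sample.int(as.integer(as.Date("2019-12-31") - as.Date("2018-01-01")), 1L)
    is_case <- stats::runif(1) < prevalence
    labels[pid] <- if (is_case) "case" else "control"
    persons[[pid]] <- data.frame(
      person_id = pid,
      birth_datetime = as.character(birth),
      gender = sample(c("male", "female"), 1L),
      race = sample(c("white", "black", "asian", "other"), 1L),
      ethnicity = sample(c("not hispanic", "hispanic"), 1L))

    plant <- function(domain, concept_id, day, element, value = NA_real_,
                      days_supply = NA_integer_) {
      if (stats::runif(1) >= capture) return(NULL)
      date <- index + day
      row <- switch(domain,
        condition = {
          conditions[[length(conditions) + 1L]] <<- data.frame(
            person_id = pid, condition_concept_id = concept_id,
            condition_start_date = as.character(date),
            condition_end_date = "")
          NULL
        },
        drug = {
          drugs[[length(drugs) + 1L]] <<- data.frame(
            person_id = pid, drug_concept_id = concept_id,
            drug_exposure_start_date = as.character(date),
            drug_exposure_end_date = "",
            days_supply = days_supply)
          NULL
        },
        procedure = {
          procedures[[length(procedures) + 1L]] <<- data.frame(
            person_id = pid, procedure_concept_id = concept_id,
            procedure_date = as.character(date))
          NULL
        },
        measurement = {
          rng <- MEASUREMENT_RANGES[[as.character(concept_id)]]
          measurements[[length(measurements) + 1L]] <<- data.frame(
            person_id = pid, measurement_concept_id = concept_id,
            measurement_date = as.character(date),
            value_as_number = value, range_low = rng[["low"]],
            range_high = rng[["high"]], unit = "")
          NULL
        },
        observation = {
          observations[[length(observations) + 1L]] <<- data.frame(
            person_id = pid, observation_concept_id = concept_id,
            observation_date = as.character(date))
          NULL
        })
      manifest[[length(manifest) + 1L]] <<- data.frame(
        person_id = pid, domain = domain, concept_id = concept_id,
        day = day, element = element)
      invisible(NULL)
    }

    if (is_case) {
      plant("condition", 1200L, 0L, "presentation")
      plant("condition", 1100L, 0L, "presentation")
      plant("condition", 1200L, -71L, "prior_history")
      plant("procedure", 3100L, 0L, "diagnostic_procedures")
      plant("measurement", 4100L, 0L, "lab_tests", value = 14.8)
      plant("measurement", 4100L, 1L, "lab_tests", value = 15.2)
      plant("measurement", 4100L, 3L, "lab_tests", value = 8.1)
      plant("drug", 2110L, 0L, "medications", days_supply = 3L)
      plant("procedure", 3200L, 2L, "treatment_procedures")
      if (stats::runif(1) < 0.5) {
        plant("condition", 1110L, 25L, "complications")
      }
      er_end <- 0L; inp_end <- 3L
    } else {
      plant("condition", 1520L, 0L, "presentation")
      plant("condition", 1100L, 0L, "presentation")  # rule-out diagnosis
      plant("condition", 1500L, -180L, "prior_history")
      plant("procedure", 3300L, 0L, "diagnostic_procedures")
      plant("measurement", 4100L, 0L, "lab_tests", value = 7.0)
      plant("drug", 2410L, 1L, "medications", days_supply = 62L)
      plant("drug", 2510L, 1L, "medications", days_supply = 2L)
      plant("condition", 1500L, 5L, "competing_diagnoses")
      er_end <- 0L; inp_end <- 2L
    }
    visits[[length(visits) + 1L]] <- data.frame(
      visit_occurrence_id = (visit_id <- visit_id + 1L), person_id = pid,
      visit_kind = "emergency room",
      visit_start_date = as.character(index),
      visit_end_date = as.character(index + er_end))
    visits[[length(visits) + 1L]] <- data.frame(
      visit_occurrence_id = (visit_id <- visit_id + 1L), person_id = pid,
      visit_kind = "inpatient",
      visit_start_date = as.character(index),
      visit_end_date = as.character(index + inp_end))

    n_noise <- stats::rpois(1L, noise_rate)
    if (n_noise > 0L) {
      for (k in seq_len(n_noise)) {
        pick <- noise_pool[sample.int(nrow(noise_pool), 1L), ]
        day <- sample.int(426L, 1L) - 366L  # uniform on [-365, 60]
        date <- index + day
        switch(pick$domain,
          condition = conditions[[length(conditions) + 1L]] <- data.frame(
            person_id = pid, condition_concept_id = pick$concept_id,
            condition_start_date = as.character(date),
            condition_end_date = ""),
          drug = drugs[[length(drugs) + 1L]] <- data.frame(
            person_id = pid, drug_concept_id = pick$concept_id,
            drug_exposure_start_date = as.character(date),
            drug_exposure_end_date = "",
            days_supply = sample.int(30L, 1L)),
          procedure = procedures[[length(procedures) + 1L]] <- data.frame(
            person_id = pid, procedure_concept_id = pick$concept_id,
            procedure_date = as.character(date)),
          measurement = {
            rng <- MEASUREMENT_RANGES[[as.character(pick$concept_id)]]
            measurements[[length(measurements) + 1L]] <- data.frame(
              person_id = pid, measurement_concept_id = pick$concept_id,
              measurement_date = as.character(date),
              value_as_number = round(stats::runif(
                1, rng[["low"]], rng[["high"]]), 1L),
              range_low = rng[["low"]], range_high = rng[["high"]],
              unit = "")
          },
          observation = observations[[length(observations) + 1L]] <- data.frame(
            person_id = pid, observation_concept_id = pick$concept_id,
            observation_date = as.character(date)))
      }
    }
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  tables <- list(
    person = do.call(rbind, persons),
    condition_occurrence = bind(conditions, data.frame(
      person_id = integer(), condition_concept_id = integer(),
      condition_start_date = character(), condition_end_date = character())),
    drug_exposure = bind(drugs, data.frame(
      person_id = integer(), drug_concept_id = integer(),
      drug_exposure_start_date = character(),
      drug_exposure_end_date = character(), days_supply = integer())),
    procedure_occurrence = bind(procedures, data.frame(
      person_id = integer(), procedure_concept_id = integer(),
      procedure_date = character())),
    measurement = bind(measurements, data.frame(
      person_id = integer(), measurement_concept_id = integer(),
      measurement_date = character(), value_as_number = numeric(),
      range_low = numeric(), range_high = numeric(), unit = character())),
    observation = bind(observations, data.frame(
      person_id = integer(), observation_concept_id = integer(),
      observation_date = character())),
    visit_occurrence = do.call(rbind, visits))
  cohort <- data.frame(
    subject_id = seq_len(n_patients),
    cohort_start_date = vapply(seq_len(n_patients), function(pid) {
      # index date is recoverable from the planted ER visit
      tables$visit_occurrence$visit_start_date[
        tables$visit_occurrence$person_id == pid][1L]
    }, character(1)))
  list(tables = tables,
       cohort = cohort,
       truth = data.frame(person_id = seq_len(n_patients), label = labels),
       manifest = if (length(manifest)) do.call(rbind, manifest) else
         data.frame(person_id = integer(), domain = character(),
                    concept_id = integer(), day = integer(),
                    element = character()))
}

#' Simulate blinded reviewers with known sensitivity and specificity
#'
#' Each reviewer labels each patient `case` with probability `sensitivity`
#' if the patient is a true case and `1 - specificity` if a control,
#' independently across reviewers, methods and patients.
#'
#' @param truth Data frame with `person_id` and `label` (as from
#'   [generate_cdm()]); an optional `study_id` column overrides the default
#'   study id (the person id as character).
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @param n_reviewers Number of reviewers.
#' @param method_labels Methods each reviewer applies to every patient.
#' @param seed Integer RNG seed.
#' @return Label data frame (`study_id`, `reviewer_id`, `method`, `round`,
#'   `label`) in the [read_labels()] schema.
#' @export
simulate_reviewers <- function(truth, sensitivity, specificity,
                               n_reviewers = 2L,
                               method_labels = c("chart", "keeper"),
                               seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_reviewers >= 1)
  study_id <- if ("study_id" %in% names(truth)) as.character(truth$study_id)
              else as.character(truth$person_id)
  is_case <- truth$label == "case"
  p_case <- ifelse(is_case, sensitivity, 1 - specificity)
  grid <- expand.grid(idx = seq_along(study_id),
                      reviewer_id = paste0("R", seq_len(n_reviewers)),
                      method = method_labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  labels <- with_seed(seed, ifelse(
    stats::runif(nrow(grid)) < p_case[grid$idx], "case", "control"))
  data.frame(study_id = study_id[grid$idx],
             reviewer_id = grid$reviewer_id,
             method = grid$method,
             round = 1L + (match(grid$method, method_labels) - 1L) %% 2L,
             label = labels)
}
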