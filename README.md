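# keeper

Structured-data patient profiles for phenotype evaluation.

## The problem

Observational research on electronic health records and claims depends on
*phenotype algorithms* — coded definitions that select the patients who have
a condition of interest. Validating a phenotype traditionally means manual
chart review: clinicians read each selected patient's full record and
adjudicate case/control status. Chart review is slow, highly variable
between reviewers, and impossible on data sources that have no charts at
all (such as administrative claims).

`keeper` implements an alternative: it converts a patient's **standardized
structured data** (OMOP Common Data Model tables) into a compact profile
organized the way a clinician reasons through a diagnosis —

1. **clinical presentation** on the day the patient sought care (day 0, the
   index date),
2. **clinical plausibility**: demographics, prior history and comorbidities
   before day 0, and competing diagnoses after it,
3. **diagnostic procedures and laboratory tests** around day 0, with lab
   values classified against their reference ranges,
4. **treatment procedures and medications** on or after day 0, drugs rolled
   up to the ingredient level with days supply, and
5. **follow-up care and complications** after day 0.

Only the information relevant to the phenotype is shown (dimensionality
reduction), extraction is identical for every condition (standardization),
and profiles are blinded with opaque study identifiers so they can be put in
front of reviewers in a randomized crossover experiment against chart
review.

The package is aimed at researchers running phenotype validation studies:
it covers the whole loop from concept-set resolution through profile
rendering to the statistical comparison of review methods, plus a synthetic
CDM generator so every step can be exercised offline.

## What it computes

**Profiles.** For each cohort entry (person, index date) and each
configured data element — a conceptual element bound to a concept set
(seed concepts expanded through the `concept_ancestor` hierarchy) and an
inclusive day-offset window `[lo, hi]` around day 0 — the package fetches
the matching events and summarizes them: measurements are grouped by
concept and reference-range qualifier (`normal` / `abnormal, high` /
`abnormal, low`), drugs are grouped by ingredient with the union of their
supply intervals as the duration, and day sets print compactly
(`day 0/1/2/5`, `day 1-5`).

**Evaluation statistics.** For a completed two-period, two-sequence
crossover experiment the package computes, per condition and pooled:

- intermethod and interrater percent agreement (one decimal, ties rounded
  away from zero),
- Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)` with the asymptotic 95% CI
  `κ ± 1.96·√(p_o(1−p_o)/(n(1−p_e)²))` (Fleiss–Cohen–Everitt variance
  available by flag),
- Fleiss's kappa over pooled reviewer pairs (equals Scott's π at two
  raters), with the Fleiss–Nee–Landis large-sample CI,
- accuracy against the gold standard,
- the Cochran–Mantel–Haenszel test across condition strata and Fisher
  exact tests per condition for method comparisons, and Student's t for
  review times.

## Worked example

```r
library(keeper)

voc    <- make_toy_vocabulary()
vocab  <- vocabulary_index(voc$concepts, voc$ancestry)
config <- toy_phenotype_config(vocab)

gen    <- generate_cdm(20, case_prevalence = 0.5, noise_rate = 5, seed = 42)
store  <- load_cdm(gen$directory, quiet = TRUE)
cohort <- read_cohort(file.path(gen$directory, "cohort.csv"))
batch  <- build_batch(cohort, config, store, vocab, seed = 42)
cat(render_profile(batch$profiles[[1]], render_options("markdown")))
```

```
# KEEPER profile ID-001 [acute appendicitis (synthetic)]

**Demographics and details about the visit:** female, 46 yo, asian, not hispanic; visit: emergency room followed by hospitalization (3 days)

## Presentation
- abdominal pain (day 0)
- acute appendicitis (day 0)
...
## Laboratory tests
- leukocytes (abnormal, high, day 0/1)
- leukocytes (normal, day 3)

## Treatment procedures
- appendectomy (day 2)

## Medications
- metronidazole (3 days)
```

This is a generated case: the index-day symptoms, the CT scan, the
leukocytosis that normalizes, the antibiotic course and the appendectomy
are the planted signature; the five-odd background noise events per patient
never appear because they lie outside every configured concept set.

Simulated reviewers close the loop:

```r
labels <- simulate_reviewers(gen$truth, sensitivity = 0.9,
                             specificity = 0.9, seed = 42)
gold   <- data.frame(study_id = gen$truth$person_id,
                     label = gen$truth$label,
                     condition = "acute appendicitis")
evaluation_report(labels, gold)
```

```
Intermethod agreement, interrater agreement and accuracy
                        Intermethod     Interrater     Interrater    Accuracy    Accuracy
Condition             n (%) / kappa          chart        profile       chart     profile
acute appendicitis       29 ( 72.5)     13 ( 65.0)     16 ( 80.0)        82.5        90.0
Overall                  29 ( 72.5)     13 ( 65.0)     16 ( 80.0)        82.5        90.0

CMH interrater (chart vs profile): chi2 = 0.489, p = 0.4844
CMH accuracy (chart vs profile):   chi2 = 0.416, p = 0.5188
```

With 20 patients and two reviewers there are 40 patient-reviewer pairs per
method, so 29 concordant pairs is 72.5% intermethod agreement; accuracy is
each method's labels against ground truth.

Command-line wrappers for the three stages live in `inst/cli/`:
`synth.R` (generate a CDM), `build-profiles.R` (CDM + cohort + config →
blinded profile files) and `evaluate.R` (labels + gold → report).

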