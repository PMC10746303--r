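test_that("loader builds the reflexive closure and validates input", {
  concepts <- data.frame(concept_id = 1:3, concept_name = c("A", "B", "C"),
                         domain_id = "condition", vocabulary_id = "SNOMED",
                         concept_class_id = "Clinical Finding")
  empty <- data.frame(ancestor_concept_id = integer(),
                      descendant_concept_id = integer())
  v <- vocabulary_index(concepts, empty)
  for (id in 1:3) expect_identical(descendants_of(v, id), id)

  dup <- rbind(concepts, concepts[1, ])
  expect_error(vocabulary_index(dup, empty), "duplicated concept_id")

  dangling <- data.frame(ancestor_concept_id = 1L,
                         descendant_concept_id = 99L)
  expect_error(vocabulary_index(concepts, dangling), "unknown concept")

  bad_domain <- concepts
  bad_domain$domain_id[2] <- "potion"
  expect_error(vocabulary_index(bad_domain, empty), "unknown domain_id")
})

test_that("chain edges close transitively: descendants(A) = {A,B,C}", {
  v <- chain_vocab()
  expect_identical(descendants_of(v, 1L), 1:3)
  expect_identical(descendants_of(v, 2L), 2:3)
  expect_identical(descendants_of(v, 3L), 3L)
})

test_that("csv loading enforces the column contract", {
  dir <- tempfile()
  dir.create(dir)
  utils::write.csv(data.frame(concept_id = 1L, concept_name = "A"),
                   file.path(dir, "concept.csv"), row.names = FALSE)
  expect_error(load_vocabulary(file.path(dir, "concept.csv")),
               "missing required column.*domain_id")
})

test_that("concept-set resolution matches hand enumeration on fixtures", {
  v <- chain_vocab()
  expect_identical(resolve_concept_set(concept_set("empty", data.frame(
    concept_id = integer())), v), integer())
  expect_identical(
    resolve_concept_set(concept_set("all", data.frame(concept_id = 1L)), v),
    1:3)
  expect_identical(
    resolve_concept_set(concept_set("seed only", data.frame(
      concept_id = 1L, include_descendants = FALSE)), v),
    1L)
  # excluded seed removes its whole subtree when include_descendants is set
  expect_identical(
    resolve_concept_set(concept_set("minus B subtree", data.frame(
      concept_id = c(1L, 2L), include_descendants = TRUE,
      excluded = c(FALSE, TRUE))), v),
    1L)
  # excluded seed alone when its include_descendants flag is off
  expect_identical(
    resolve_concept_set(concept_set("minus B only", data.frame(
      concept_id = c(1L, 2L), include_descendants = c(TRUE, FALSE),
      excluded = c(FALSE, TRUE))), v),
    c(1L, 3L))
  expect_error(
    resolve_concept_set(concept_set("bad", data.frame(concept_id = 42L)), v),
    "unknown seed")
})

test_that("resolution equals brute-force ancestor filtering and is monotone", {
  v <- toy_vocab()
  all_ids <- v$concepts$concept_id
  brute <- function(seed_ids) {
    sort(Filter(function(id) {
      any(v$ancestry$ancestor_concept_id %in% seed_ids &
            v$ancestry$descendant_concept_id == id)
    }, all_ids))
  }
  set.seed(11)
  for (rep in 1:20) {
    seeds <- sample(all_ids, sample(1:4, 1))
    cs <- concept_set("r", data.frame(concept_id = seeds))
    resolved <- resolve_concept_set(cs, v)
    expect_identical(resolved, as.integer(brute(seeds)))
    # monotone: adding a non-excluded seed never shrinks the set
    extra <- sample(setdiff(all_ids, seeds), 1)
    bigger <- resolve_concept_set(
      concept_set("r+", data.frame(concept_id = c(seeds, extra))), v)
    expect_true(all(resolved %in% bigger))
  }
})

test_that("ingredient rollup is reflexive, idempotent, and flags ambiguity", {
  v <- toy_vocab()
  expect_identical(ingredient_of(2100L, v), 2100L)    # ingredient itself
  expect_identical(ingredient_of(2110L, v), 2100L)    # product -> ingredient
  expect_true(is.na(ingredient_of(2000L, v)))         # class has no ingredient
  expect_error(ingredient_of(1100L, v), "domain")
  # idempotence wherever defined
  for (id in v$concepts$concept_id[v$concepts$domain_id == "drug"]) {
    ing <- ingredient_of(id, v)
    if (!is.na(ing)) expect_identical(ingredient_of(ing, v), ing)
  }
  # a combination product with two ingredient ancestors is an error
  concepts <- data.frame(
    concept_id = 1:3,
    concept_name = c("amoxicillin", "clavulanate", "amoxicillin/clavulanate"),
    domain_id = "drug", vocabulary_id = "RxNorm",
    concept_class_id = c("Ingredient", "Ingredient", "Clinical Drug"))
  ancestry <- data.frame(ancestor_concept_id = c(1L, 2L),
                         descendant_concept_id = c(3L, 3L))
  combo <- vocabulary_index(concepts, ancestry)
  expect_error(ingredient_of(3L, combo), "multiple ingredient")
})

test_that("prevalence report counts events and patients and sorts correctly", {
  empty <- concept_prevalence_report(integer(), data.frame(
    person_id = integer(), concept_id = integer()))
  expect_identical(nrow(empty), 0L)

  events <- data.frame(person_id = c(1L, 1L),
                       concept_id = c(10L, 10L))
  rep1 <- concept_prevalence_report(10L, events)
  expect_identical(rep1$event_count, 2L)
  expect_identical(rep1$person_count, 1L)

  # counts {5, 0, 2} across patients -> rows ordered 5, 2, 0
  events <- data.frame(
    person_id = c(1:5, 6:7),
    concept_id = c(rep(10L, 5), rep(30L, 2)))
  rep3 <- concept_prevalence_report(c(10L, 20L, 30L), events)
  expect_identical(rep3$concept_id, c(10L, 30L, 20L))
  expect_identical(rep3$person_count, c(5L, 2L, 0L))
})
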