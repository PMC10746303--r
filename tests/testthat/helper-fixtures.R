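# Shared fixtures and independent oracles, all built in code at test time.

toy_vocab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      voc <- make_toy_vocabulary()
      cache <<- vocabulary_index(voc$concepts, voc$ancestry)
    }
    cache
  }
})

# minimal 3-node chain vocabulary A(1) -> B(2) -> C(3), direct edges only
chain_vocab <- function() {
  concepts <- data.frame(
    concept_id = 1:3,
    concept_name = c("A", "B", "C"),
    domain_id = "condition",
    vocabulary_id = "SNOMED",
    concept_class_id = "Clinical Finding")
  ancestry <- data.frame(ancestor_concept_id = c(1L, 2L),
                         descendant_concept_id = c(2L, 3L))
  vocabulary_index(concepts, ancestry)
}

write_cdm_fixture <- function(tables, dir = tempfile("cdm_fix_")) {
  dir.create(dir)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  dir
}

# two in-memory patients whose profiles reproduce the worked-profile cell
# strings (short antibiotic course, slashed and dashed lab day sets, ER ->
# hospitalization visit summary)
worked_profile_store <- function() {
  idx1 <- as.Date("2018-06-01")  # patient 1 index
  idx2 <- as.Date("2018-09-10")  # patient 2 index
  d1 <- function(k) as.character(idx1 + k)
  d2 <- function(k) as.character(idx2 + k)
  tables <- list(
    person = data.frame(
      person_id = 1:2,
      birth_datetime = c("1972-01-15", "2001-02-20"),
      gender = c("male", "female"),
      race = c("white", "white"),
      ethnicity = c("not hispanic", "not hispanic")),
    visit_occurrence = data.frame(
      visit_occurrence_id = 1:3,
      person_id = c(1L, 1L, 2L),
      visit_kind = c("emergency room", "inpatient", "inpatient"),
      visit_start_date = c(d1(0), d1(0), d2(0)),
      visit_end_date = c(d1(0), d1(3), d2(7))),
    condition_occurrence = data.frame(
      person_id = c(1L, 1L, 1L, 1L, 1L, 1L, 1L,
                    2L, 2L, 2L, 2L),
      condition_concept_id = c(1200L, 1100L, 1320L, 1200L, 1200L, 1110L, 1400L,
                               1200L, 1100L, 1300L, 1300L),
      condition_start_date = c(d1(0), d1(0), d1(0), d1(-71), d1(-1), d1(25),
                               d1(25),
                               d2(0), d2(0), d2(-182), d2(20)),
      condition_end_date = ""),
    procedure_occurrence = data.frame(
      person_id = c(1L, 1L, 2L),
      procedure_concept_id = c(3100L, 3200L, 3100L),
      procedure_date = c(d1(0), d1(25), d2(5))),
    drug_exposure = data.frame(
      person_id = c(1L, 2L),
      drug_concept_id = c(2110L, 2210L),
      drug_exposure_start_date = c(d1(0), d2(0)),
      drug_exposure_end_date = "",
      days_supply = c(3L, 5L)),
    measurement = data.frame(
      person_id = c(1L,
                    rep(2L, 4L), rep(2L, 4L), rep(2L, 5L)),
      measurement_concept_id = c(4100L,
                                 rep(4100L, 8L), rep(4300L, 5L)),
      measurement_date = c(d1(1),
                           d2(0), d2(1), d2(2), d2(5),
                           d2(3), d2(4), d2(6), d2(7),
                           d2(1), d2(2), d2(3), d2(4), d2(5)),
      value_as_number = c(15.2,
                          rep(14.1, 4L), rep(8.0, 4L), rep(88, 5L)),
      range_low = c(rep(4, 9L), rep(40, 5L)),
      range_high = c(rep(11, 9L), rep(75, 5L)),
      unit = ""))
  dir <- write_cdm_fixture(tables)
  list(store = load_cdm(dir, quiet = TRUE),
       cohort = data.frame(person_id = 1:2, index_date = c(idx1, idx2)))
}

# -- independent oracles ------------------------------------------------------

# Scott's pi for two raters over parallel label vectors
scott_pi <- function(l1, l2) {
  stopifnot(length(l1) == length(l2))
  po <- mean(l1 == l2)
  lv <- unique(c(l1, l2))
  pj <- vapply(lv, function(v) (sum(l1 == v) + sum(l2 == v)) /
                 (2 * length(l1)), numeric(1))
  pe <- sum(pj^2)
  (po - pe) / (1 - pe)
}

# Cohen's kappa by direct hand arithmetic on a 2x2
cohen_by_hand <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- ((tab[1, 1] + tab[1, 2]) * (tab[1, 1] + tab[2, 1]) +
           (tab[2, 1] + tab[2, 2]) * (tab[1, 2] + tab[2, 2])) / n^2
  (po - pe) / (1 - pe)
}

# two-sided Fisher exact p by full hypergeometric enumeration
fisher_by_enumeration <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# classical single-table Mantel-Haenszel chi-square
mh_single_formula <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  (n - 1) * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force windowed filter used to re-verify profile sections
brute_force_events <- function(store, person_id, spec, index_date) {
  ev <- store$events
  ev <- ev[ev$person_id == person_id &
             ev$domain %in% spec$domains &
             ev$concept_id %in% spec$resolved_ids, , drop = FALSE]
  off <- as.integer(ev$start_date - as.Date(index_date))
  ev[off >= spec$window$lo & off <= spec$window$hi, , drop = FALSE]
}

# build a complete 2-reviewer crossover label set with planted intermethod
# concordance per condition
planted_labels <- function(concord_per_cond, n_per_cond = 20L) {
  labels <- list()
  gold <- list()
  for (ci in seq_along(concord_per_cond)) {
    cond <- names(concord_per_cond)[ci]
    ids <- sprintf("%s-%02d", cond, seq_len(n_per_cond))
    gold[[cond]] <- data.frame(study_id = ids, label = "case",
                               condition = cond)
    revs <- paste0(cond, c("-r1", "-r2"))
    slots <- expand.grid(study_id = ids, reviewer_id = revs,
                         stringsAsFactors = FALSE)  # 40 chart/keeper pairs
    agree <- seq_len(nrow(slots)) <= concord_per_cond[[ci]]
    for (m in c("chart", "keeper")) {
      lab <- if (m == "chart") rep("case", nrow(slots)) else
        ifelse(agree, "case", "control")
      labels[[paste(cond, m)]] <- data.frame(
        study_id = slots$study_id, reviewer_id = slots$reviewer_id,
        method = m, round = if (m == "chart") 1L else 2L, label = lab)
    }
  }
  list(labels = do.call(rbind, labels), gold = do.call(rbind, gold))
}

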