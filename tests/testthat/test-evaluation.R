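test_that("percent rounds half away from zero to one decimal", {
  expect_identical(percent(141, 160), 88.1)
  expect_identical(percent(20, 20), 100)
  expect_identical(percent(0, 20), 0)
  expect_identical(percent(139, 160), 86.9)
  expect_identical(percent(61, 80), 76.3)   # 76.25 ties away from zero
  expect_identical(percent(73, 80), 91.3)   # 91.25 likewise
  # scale consistency
  for (k in c(2, 5, 10)) expect_identical(percent(k * 7, k * 40),
                                          percent(7, 40))
  expect_error(percent(1, 0), "positive")
  expect_error(percent(5, 4), "n_agree")
})

test_that("Cohen's kappa matches hand arithmetic and is transpose-invariant", {
  perfect <- cohen_kappa(two_by_two(10, 0, 0, 10))
  expect_identical(perfect$kappa, 1)

  k <- cohen_kappa(two_by_two(20, 5, 10, 15))
  expect_equal(k$kappa, 0.4)           # po 0.7, pe 0.5
  expect_equal(k$percent, 70)

  balanced <- cohen_kappa(two_by_two(9, 1, 81, 9))  # po = pe -> kappa 0
  expect_equal(balanced$kappa, 0)

  set.seed(8)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    k1 <- cohen_kappa(tab)
    expect_equal(k1$kappa, cohen_by_hand(tab))
    expect_equal(cohen_kappa(t(tab))$kappa, k1$kappa)
    expect_true(k1$kappa >= -1 && k1$kappa <= 1)
    expect_true(k1$ci_low <= k1$kappa && k1$kappa <= k1$ci_high)
  }
  # the asymptotic CI: kappa +/- 1.959964 * sqrt(po(1-po)/(n(1-pe)^2))
  tab <- two_by_two(20, 5, 10, 15)
  se <- sqrt(0.7 * 0.3 / (50 * 0.25))
  k <- cohen_kappa(tab)
  expect_equal(k$ci_low, 0.4 - qnorm(0.975) * se)
  expect_equal(k$ci_high, 0.4 + qnorm(0.975) * se)
  # the Fleiss-Cohen-Everitt variance flag gives a finite, nearby interval
  kf <- cohen_kappa(tab, variance = "fleiss")
  expect_true(kf$ci_low < kf$kappa && kf$kappa < kf$ci_high)
})

test_that("Fleiss's kappa reduces to Scott's pi at two raters", {
  all_agree <- matrix(c(2, 0, 0, 2, 2, 0), ncol = 2, byrow = TRUE)
  expect_identical(fleiss_kappa(all_agree, 2)$kappa, 1)

  set.seed(15)
  for (i in 1:20) {
    n <- 40
    l1 <- sample(c("case", "control"), n, replace = TRUE, prob = c(.6, .4))
    l2 <- ifelse(runif(n) < 0.7, l1,
                 sample(c("case", "control"), n, replace = TRUE))
    counts <- cbind(case = (l1 == "case") + (l2 == "case"),
                    control = (l1 == "control") + (l2 == "control"))
    expect_equal(fleiss_kappa(counts, 2)$kappa, scott_pi(l1, l2))
  }

  # a single split subject has no within-subject agreement
  split1 <- matrix(c(1, 1), ncol = 2)
  expect_true(fleiss_kappa(split1, 2)$kappa <= 0)

  expect_error(fleiss_kappa(matrix(c(2, 0, 1, 0), ncol = 2, byrow = TRUE), 2),
               "exactly 2 ratings")
})

test_that("accuracy counts gold-standard matches and names missing ids", {
  gold <- data.frame(study_id = c("a", "b", "c"),
                     label = c("case", "case", "control"))
  labels <- data.frame(study_id = c("a", "b", "c"),
                       label = c("case", "control", "control"))
  expect_identical(accuracy(labels, gold), 66.7)
  expect_identical(accuracy(gold, gold), 100)
  flipped <- transform(gold, label = ifelse(label == "case", "control",
                                            "case"))
  expect_identical(accuracy(flipped, gold), 0)
  expect_error(accuracy(data.frame(study_id = "zz", label = "case"), gold),
               "zz")
})

test_that("CMH reduces to the single-table formula and scales additively", {
  tab <- matrix(c(10, 5, 3, 12), 2, byrow = TRUE)
  got <- cmh_test(tab, correct = FALSE)
  expect_equal(got$statistic, mh_single_formula(tab))

  # independent cross-check against the standard implementation
  arr <- array(c(10, 3, 5, 12, 8, 2, 6, 9), dim = c(2, 2, 2))
  strata <- list(matrix(c(10, 5, 3, 12), 2, byrow = TRUE),
                 matrix(c(8, 6, 2, 9), 2, byrow = TRUE))
  for (corr in c(TRUE, FALSE)) {
    ours <- cmh_test(strata, correct = corr)
    ref <- stats::mantelhaen.test(arr, correct = corr)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }

  # a stratum with an all-zero margin contributes nothing
  degenerate <- matrix(c(0, 0, 4, 6), 2, byrow = TRUE)
  with_dg <- cmh_test(c(strata, list(degenerate)), correct = FALSE)
  expect_equal(with_dg$statistic, cmh_test(strata, correct = FALSE)$statistic)
  expect_identical(with_dg$n_strata_used, 2L)
  expect_error(cmh_test(degenerate), "degenerate")

  # duplicating every stratum doubles the uncorrected statistic
  doubled <- cmh_test(c(strata, strata), correct = FALSE)
  expect_equal(doubled$statistic,
               2 * cmh_test(strata, correct = FALSE)$statistic)
})

test_that("Fisher exact follows the probability-ordering two-sided rule", {
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), 34 / 70, tolerance = 1e-7)
  expect_equal(fisher_exact(tab), fisher_by_enumeration(tab),
               tolerance = 1e-7)
  # zero row margin leaves a single feasible table
  expect_identical(fisher_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1)
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact(tab)
    expect_true(p >= 0 && p <= 1)
    expect_equal(p, fisher_by_enumeration(tab), tolerance = 1e-7)
  }
})

test_that("review-time comparison matches pooled-variance hand arithmetic", {
  same <- review_time_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  paired <- review_time_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_identical(paired$t, 0)

  out <- review_time_test(c(10, 12, 14), c(20, 22, 24))
  expect_equal(out$t, -10 / (2 * sqrt(2 / 3)), tolerance = 1e-6)
  expect_equal(out$df, 4)
  expect_equal(out$mean_a, 12)
  expect_equal(out$sd_b, 2)
  expect_error(review_time_test(1, c(2, 3)), "at least 2")
  expect_error(review_time_test(c(1, 2), c(2, 3, 4), paired = TRUE),
               "equal-length")
})

test_that("crossover assignment halves, swaps and reproduces per seed", {
  ids <- sprintf("ID-%02d", 1:20)
  a1 <- assign_crossover(ids, seed = 42)
  expect_identical(length(a1$group_a), 10L)
  expect_identical(length(a1$group_b), 10L)
  expect_identical(sort(c(a1$group_a, a1$group_b)), sort(ids))
  expect_identical(a1, assign_crossover(ids, seed = 42))
  expect_false(identical(a1$group_a, assign_crossover(ids, seed = 1)$group_a))

  # every patient sees both methods across the two rounds
  for (id in ids) {
    methods <- c(method_for(a1, 1, id), method_for(a1, 2, id))
    expect_setequal(methods, c("keeper", "chart"))
  }
  odd <- assign_crossover(sprintf("x%d", 1:7), seed = 1)
  expect_identical(abs(length(odd$group_a) - length(odd$group_b)), 1L)
  expect_error(assign_crossover(c("a", "a", "b"), 1), "duplicate")
})

test_that("evaluation report recovers planted agreement structure", {
  # full agreement everywhere -> all percents 100, all kappas 1
  ids <- sprintf("p%02d", 1:10)
  gold <- data.frame(study_id = ids, label = rep(c("case", "control"), 5),
                     condition = "cond1")
  all_labels <- expand.grid(study_id = ids, reviewer_id = c("r1", "r2"),
                            method = c("chart", "keeper"),
                            stringsAsFactors = FALSE)
  all_labels$round <- ifelse(all_labels$method == "chart", 1L, 2L)
  all_labels$label <- gold$label[match(all_labels$study_id, gold$study_id)]
  rep1 <- evaluation_report(all_labels, gold)
  expect_true(all(rep1$table$intermethod_pct == 100))
  expect_true(all(rep1$table$interrater_chart_kappa == 1))
  expect_true(all(rep1$table$interrater_keeper_kappa == 1))
  expect_true(all(rep1$table$accuracy_chart_pct == 100))

  # planted per-condition concordance 32/38/34/37 of 40 -> pooled 88.1%
  planted <- planted_labels(c(dm1 = 32L, appendicitis = 38L, copd = 34L,
                              esrd = 37L))
  rep2 <- evaluation_report(planted$labels, planted$gold)
  overall <- rep2$table[rep2$table$condition == "Overall", ]
  expect_identical(overall$intermethod_n_agree, 141L)
  expect_identical(overall$intermethod_pct, 88.1)
  expect_identical(
    rep2$table$intermethod_pct[rep2$table$condition == "dm1"], 80)
  expect_identical(
    rep2$table$intermethod_pct[rep2$table$condition == "appendicitis"], 95)

  # incomplete designs are rejected with the missing cells listed
  broken <- planted$labels[-1, ]
  expect_error(evaluation_report(broken, planted$gold), "missing label cells")
})

test_that("independent reviewers give near-zero kappa on average", {
  # permutation-style check: labels independent of each other
  set.seed(99)
  kappas <- replicate(300, {
    tab <- table(factor(sample(c("case", "control"), 40, TRUE), c("case", "control")),
                 factor(sample(c("case", "control"), 40, TRUE), c("case", "control")))
    cohen_kappa(tab)$kappa
  })
  expect_lt(abs(mean(kappas)), 0.05)
})
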