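# Evaluation apparatus: crossover assignment, percent agreement, Cohen's and
# Fleiss's kappa with 95% CIs, accuracy vs gold standard, and the stratified
# (CMH) / pairwise (Fisher) method comparisons.

#' Percentage rounded to one decimal, half away from zero
#'
#' @param n_agree Numerator count.
#' @param n Denominator count (> 0).
#' @return `100 * n_agree / n` rounded to one decimal, ties away from zero.
#' @export
percent <- function(n_agree, n) {
  if (length(n) != 1L || n <= 0) stop("n must be positive", call. = FALSE)
  if (n_agree < 0 || n_agree > n) {
    stop("n_agree must lie in [0, n]", call. = FALSE)
  }
  round_half_away(100 * n_agree / n, 1L)
}

round_half_away <- function(x, digits = 1L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' A 2x2 agreement table
#'
#' Rows are rater/method 1 (case, control); columns rater/method 2.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = both case, `b` =
#'   row case/column control, `c` = row control/column case, `d` = both
#'   control.
#' @return A 2x2 integer matrix with case/control dimnames.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  matrix(as.integer(counts), nrow = 2L, byrow = TRUE,
         dimnames = list(rater1 = c("case", "control"),
                         rater2 = c("case", "control")))
}

agreement_result <- function(n, n_agree, kappa, ci_low, ci_high,
                             statistic_name) {
  structure(list(n = as.integer(n), n_agree = as.integer(n_agree),
                 percent = percent(n_agree, n),
                 kappa = kappa,
                 ci_low = max(-1, ci_low), ci_high = min(1, ci_high),
                 statistic_name = statistic_name),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d agree (%.1f%%), kappa %.3f (95%% CI %.3f to %.3f)\n",
              x$statistic_name, x$n_agree, x$n, x$percent, x$kappa,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two raters (or two methods):
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po = (a + d) / n`
#' and chance agreement `pe` from the marginal products. Perfect agreement on
#' a degenerate margin (`po = pe = 1`) is defined as kappa 1. The default
#' 95% CI uses the simple asymptotic standard error
#' `sqrt(po (1 - po) / (n (1 - pe)^2))`; `variance = "fleiss"` selects the
#' Fleiss-Cohen-Everitt large-sample variance instead. The CI is truncated
#' to `[-1, 1]`.
#'
#' @param table A 2x2 matrix (see [two_by_two()]).
#' @param variance `"asymptotic"` (default) or `"fleiss"`.
#' @return An `agreement_result`.
#' @export
cohen_kappa <- function(table, variance = c("asymptotic", "fleiss")) {
  variance <- match.arg(variance)
  table <- as.matrix(table)
  stopifnot(nrow(table) == ncol(table))
  n <- sum(table)
  if (n == 0) stop("empty table", call. = FALSE)
  p <- table / n
  po <- sum(diag(p))
  rowm <- rowSums(p)
  colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (pe == 1) {
    if (po == 1) {
      return(agreement_result(n, sum(diag(table)), 1, 1, 1, "Cohen's kappa"))
    }
    stop("kappa undefined: chance agreement is 1 but observed is not",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  se <- if (variance == "asymptotic") {
    sqrt(po * (1 - po) / (n * (1 - pe)^2))
  } else {
    # Fleiss, Cohen & Everitt large-sample variance
    k <- nrow(p)
    A <- sum(vapply(seq_len(k), function(i) {
      p[i, i] * (1 - (rowm[i] + colm[i]) * (1 - kappa))^2
    }, numeric(1)))
    B <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) B <- B + p[i, j] * (colm[i] + rowm[j])^2
    }
    B <- (1 - kappa)^2 * B
    C <- (kappa - pe * (1 - kappa))^2
    sqrt(max(A + B - C, 0) / (n * (1 - pe)^2))
  }
  z <- stats::qnorm(0.975)
  agreement_result(n, sum(diag(table)), kappa, kappa - z * se,
                   kappa + z * se, "Cohen's kappa")
}

#' Fleiss's kappa for multiple raters with pooled marginals
#'
#' Standard Fleiss formula on per-subject category counts: each subject `i`
#' contributes agreement `P_i = sum_j n_ij (n_ij - 1) / (m (m - 1))`;
#' `kappa = (mean(P_i) - Pe) / (1 - Pe)` with `Pe = sum_j p_j^2` from the
#' pooled category proportions. The 95% CI uses the Fleiss-Nee-Landis
#' large-sample variance. With two raters Fleiss's kappa equals Scott's pi.
#'
#' @param ratings Matrix (subjects x categories) of rating counts; every row
#'   must sum to `raters_per_subject`.
#' @param raters_per_subject Number of ratings per subject, `m >= 2`.
#' @return An `agreement_result` (its `n_agree` counts subjects on which all
#'   raters agree).
#' @export
fleiss_kappa <- function(ratings, raters_per_subject) {
  ratings <- as.matrix(ratings)
  m <- as.integer(raters_per_subject)
  if (m < 2L) stop("need at least 2 raters per subject", call. = FALSE)
  if (any(rowSums(ratings) != m)) {
    stop("every subject must have exactly ", m, " ratings", call. = FALSE)
  }
  N <- nrow(ratings)
  if (N == 0L) stop("no subjects", call. = FALSE)
  Pi <- rowSums(ratings * (ratings - 1)) / (m * (m - 1))
  Pbar <- mean(Pi)
  pj <- colSums(ratings) / (N * m)
  Pe <- sum(pj^2)
  if (Pe == 1) {
    if (Pbar == 1) {
      return(agreement_result(N, N, 1, 1, 1, "Fleiss's kappa"))
    }
    stop("kappa undefined: chance agreement is 1 but observed is not",
         call. = FALSE)
  }
  kappa <- (Pbar - Pe) / (1 - Pe)
  var_k <- 2 / (N * m * (m - 1)) *
    (Pe - (2 * m - 3) * Pe^2 + 2 * (m - 2) * sum(pj^3)) / (1 - Pe)^2
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(0.975)
  agreement_result(N, sum(apply(ratings, 1L, max) == m), kappa,
                   kappa - z * se, kappa + z * se, "Fleiss's kappa")
}

#' Accuracy of review labels against the gold standard
#'
#' @param labels Data frame with `study_id` and `label` columns (one row per
#'   reviewed patient-label).
#' @param gold Named character vector `study_id -> label`, or a data frame
#'   with `study_id` and `label`.
#' @return One-decimal percentage of labels matching the gold standard.
#' @export
accuracy <- function(labels, gold) {
  if (is.data.frame(gold)) {
    gold <- stats::setNames(as.character(gold$label),
                            as.character(gold$study_id))
  }
  ids <- as.character(labels$study_id)
  missing <- unique(ids[!ids %in% names(gold)])
  if (length(missing)) {
    stop("no gold label for study id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  percent(sum(as.character(labels$label) == gold[ids]), nrow(labels))
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Chi-square statistic on 2x2xK:
#' `((|sum(a_k - E a_k)| - correction)^2) / sum(Var a_k)` with expectation
#' and variance from the hypergeometric margins of each stratum. Strata with
#' an all-zero margin (zero variance) contribute nothing and are skipped.
#' The continuity correction (0.5, clamped at the absolute deviation) is on
#' by default; p is from chi-square with 1 df.
#'
#' @param strata A single 2x2 matrix or a list of them.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `statistic`, `p_value`, `df`, `n_strata_used`.
#' @export
cmh_test <- function(strata, correct = TRUE) {
  if (is.matrix(strata)) strata <- list(strata)
  sumA <- sumE <- sumV <- 0
  used <- 0L
  for (tab in strata) {
    tab <- as.matrix(tab)
    stopifnot(all(dim(tab) == 2L))
    n <- sum(tab)
    r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
    c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
    if (n < 2 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
    sumA <- sumA + tab[1L, 1L]
    sumE <- sumE + r1 * c1 / n
    sumV <- sumV + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    used <- used + 1L
  }
  if (sumV == 0) {
    stop("all strata are degenerate (zero-margin or singleton)",
         call. = FALSE)
  }
  delta <- abs(sumA - sumE)
  yates <- if (correct) min(0.5, delta) else 0
  statistic <- (delta - yates)^2 / sumV
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE),
       df = 1L, n_strata_used = used)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the "probability at most that of the observed table"
#' rule over all tables with the same margins (the common software
#' convention, within relative tolerance 1e-7).
#'
#' @param table A 2x2 matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  # guard against floating-point accumulation nudging the sum past 1
  min(stats::fisher.test(table)$p.value, 1)
}

#' Compare review times between methods with Student's t-test
#'
#' Unpaired pooled-variance t-test by default; paired t-test on the
#' differences when `paired` is set.
#'
#' @param times_a,times_b Review times in minutes (>= 2 observations per
#'   arm; equal lengths when paired).
#' @param paired Use the paired test.
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p`.
#' @export
review_time_test <- function(times_a, times_b, paired = FALSE) {
  if (length(times_a) < 2L || length(times_b) < 2L) {
    stop("need at least 2 observations per arm", call. = FALSE)
  }
  if (paired && length(times_a) != length(times_b)) {
    stop("paired test requires equal-length arms", call. = FALSE)
  }
  ht <- if (identical(times_a, times_b)) {
    # degenerate identical arms: difference is exactly zero
    list(statistic = c(t = 0),
         parameter = c(df = if (paired) length(times_a) - 1L else
           length(times_a) + length(times_b) - 2L),
         p.value = 1)
  } else {
    stats::t.test(times_a, times_b, paired = paired, var.equal = TRUE)
  }
  list(mean_a = mean(times_a), sd_a = stats::sd(times_a),
       mean_b = mean(times_b), sd_b = stats::sd(times_b),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-period, two-sequence crossover assignment
#'
#' Shuffles the study ids with a seeded uniform permutation and halves them:
#' in round 1 group A reviews profiles while group B reviews charts; in
#' round 2 the methods swap, so every patient is reviewed by each method
#' exactly once per reviewer.
#'
#' @param study_ids Vector of at least two distinct study ids (an odd count
#'   makes the groups differ by one).
#' @param seed Integer RNG seed.
#' @param washout_days Metadata only: the minimum washout between rounds.
#' @return An object of class `crossover_assignment` with `group_a`,
#'   `group_b`, a `schedule` data frame (`round`, `group`, `method`) and
#'   `washout_days`.
#' @export
assign_crossover <- function(study_ids, seed, washout_days = 7L) {
  study_ids <- as.character(study_ids)
  if (anyDuplicated(study_ids)) {
    stop("duplicate study ids: ",
         paste(unique(study_ids[duplicated(study_ids)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(study_ids)
  if (n < 2L) stop("need at least 2 study ids", call. = FALSE)
  shuffled <- with_seed(seed, sample(study_ids))
  half <- n %/% 2L
  assignment <- structure(list(
    group_a = sort(shuffled[seq_len(half)]),
    group_b = sort(shuffled[(half + 1L):n]),
    schedule = data.frame(round = c(1L, 1L, 2L, 2L),
                          group = c("a", "b", "a", "b"),
                          method = c("keeper", "chart", "chart", "keeper")),
    washout_days = as.integer(washout_days),
    seed = as.integer(seed)),
    class = "crossover_assignment")
  assignment
}

#' @export
print.crossover_assignment <- function(x, ...) {
  cat("<crossover_assignment> 2-period, 2-sequence;",
      length(x$group_a), "+", length(x$group_b), "patients, washout >=",
      x$washout_days, "days\n")
  print(x$schedule, row.names = FALSE)
  invisible(x)
}

#' Which method a group uses in a given round
#'
#' @param assignment A `crossover_assignment`.
#' @param round Round number (1 or 2).
#' @param study_id A study id in the assignment.
#' @return `"keeper"` or `"chart"`.
#' @export
method_for <- function(assignment, round, study_id) {
  grp <- if (study_id %in% assignment$group_a) "a"
  else if (study_id %in% assignment$group_b) "b"
  else stop("unknown study id: ", study_id, call. = FALSE)
  sched <- assignment$schedule
  sched$method[sched$round == round & sched$group == grp]
}
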