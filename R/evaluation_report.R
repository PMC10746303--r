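# Per-condition and pooled evaluation report: intermethod agreement,
# interrater agreement per method, accuracy vs gold standard, and the
# stratified / pairwise method comparisons.

#' Read a reviewer label CSV
#'
#' @param path CSV with columns `study_id`, `reviewer_id`, `method`
#'   (`chart`/`keeper`), `round` (1/2), `label` (`case`/`control`) and
#'   optionally `review_time_minutes`.
#' @return Validated data frame.
#' @export
read_labels <- function(path) {
  df <- read_keeper_csv(path)
  require_columns(df, c("study_id", "reviewer_id", "method", "round",
                        "label"), basename(path))
  validate_labels(df)
}

validate_labels <- function(df) {
  df$study_id <- as.character(df$study_id)
  df$reviewer_id <- as.character(df$reviewer_id)
  df$method <- as.character(df$method)
  df$label <- as.character(df$label)
  bad <- setdiff(unique(df$method), c("chart", "keeper"))
  if (length(bad)) stop("unknown method value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$label), c("case", "control"))
  if (length(bad)) stop("unknown label value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(df$study_id, df$reviewer_id, df$method)
  if (anyDuplicated(key)) {
    stop("duplicate label for (study_id, reviewer_id, method): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  df
}

#' Read a gold-standard CSV
#'
#' @param path CSV with columns `study_id`, `label`, `condition`.
#' @return Validated data frame.
#' @export
read_gold <- function(path) {
  df <- read_keeper_csv(path)
  require_columns(df, c("study_id", "label", "condition"), basename(path))
  df$study_id <- as.character(df$study_id)
  df$label <- as.character(df$label)
  df$condition <- as.character(df$condition)
  if (anyDuplicated(df$study_id)) {
    stop("duplicate study_id in gold standard", call. = FALSE)
  }
  df
}

label_lookup <- function(labels) {
  stats::setNames(labels$label,
                  paste(labels$study_id, labels$reviewer_id, labels$method))
}

agree_table <- function(x, y) {
  lv <- c("case", "control")
  table(factor(x, lv), factor(y, lv))
}

#' Full evaluation report over a completed crossover experiment
#'
#' Computes, per condition and pooled over all conditions: intermethod
#' agreement (each reviewer's chart label vs their profile label for the same
#' patient; percent and Cohen's kappa), interrater agreement per method
#' (the two reviewers' labels per patient; Cohen's kappa per condition,
#' Fleiss's kappa pooled over reviewer pairs for the overall row), and
#' accuracy of each method against the gold standard. Interrater agreement
#' and accuracy are compared between methods with the Cochran-Mantel-Haenszel
#' test stratified by condition, followed by per-condition Fisher exact
#' tests.
#'
#' @param labels Label data frame as from [read_labels()]; the design must
#'   be complete (two reviewers per condition, every reviewer labeling every
#'   patient with both methods).
#' @param gold Gold-standard data frame as from [read_gold()].
#' @param continuity_correction Continuity correction for [cmh_test()].
#' @param fleiss_pooling `"pooled"` (default: one Fleiss kappa over the
#'   pooled subjects of all reviewer pairs) or `"averaged"` (mean of the
#'   per-condition Cohen's kappas, no CI).
#' @return An object of class `keeper_evaluation`: a list with `table`
#'   (one row per condition plus `Overall`), `comparisons` (CMH and Fisher
#'   results) and `details` (the underlying `agreement_result` objects).
#' @export
evaluation_report <- function(labels, gold,
                              continuity_correction = TRUE,
                              fleiss_pooling = c("pooled", "averaged")) {
  fleiss_pooling <- match.arg(fleiss_pooling)
  labels <- validate_labels(as.data.frame(labels))
  gold <- as.data.frame(gold)
  conditions <- unique(gold$condition)
  lookup <- label_lookup(labels)
  gold_map <- stats::setNames(gold$label, gold$study_id)

  # design completeness: every reviewer of a condition labels every patient
  # of that condition with both methods
  missing <- character()
  cond_reviewers <- list()
  for (cond in conditions) {
    ids <- gold$study_id[gold$condition == cond]
    revs <- sort(unique(labels$reviewer_id[labels$study_id %in% ids]))
    if (length(revs) != 2L) {
      stop("condition '", cond, "': expected exactly 2 reviewers, found ",
           length(revs), call. = FALSE)
    }
    cond_reviewers[[cond]] <- revs
    for (id in ids) for (r in revs) for (m in c("chart", "keeper")) {
      if (is.na(lookup[paste(id, r, m)])) {
        missing <- c(missing, paste(cond, id, r, m, sep = "/"))
      }
    }
  }
  if (length(missing)) {
    stop("incomplete design; missing label cells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  details <- list()
  rows <- list()
  inter_strata <- list()   # condition-stratified interrater agree/disagree
  acc_strata <- list()     # condition-stratified accuracy correct/incorrect
  fisher_p <- numeric(0)
  pooled_intermethod <- matrix(0L, 2L, 2L)
  pooled_interrater <- list(chart = NULL, keeper = NULL)  # Fleiss count rows
  pooled_acc <- list(chart = c(0L, 0L), keeper = c(0L, 0L))
  per_cond_cohen <- list(chart = numeric(0), keeper = numeric(0))

  for (cond in conditions) {
    ids <- gold$study_id[gold$condition == cond]
    revs <- cond_reviewers[[cond]]
    lab <- function(id, r, m) lookup[[paste(id, r, m)]]

    # intermethod: chart vs profile per (patient, reviewer)
    chart_l <- unlist(lapply(ids, function(id)
      vapply(revs, function(r) lab(id, r, "chart"), character(1))))
    keeper_l <- unlist(lapply(ids, function(id)
      vapply(revs, function(r) lab(id, r, "keeper"), character(1))))
    im_tab <- agree_table(chart_l, keeper_l)
    im <- cohen_kappa(im_tab)
    pooled_intermethod <- pooled_intermethod + im_tab

    # interrater per method: reviewer 1 vs reviewer 2 per patient
    ir <- list()
    for (m in c("chart", "keeper")) {
      l1 <- vapply(ids, function(id) lab(id, revs[1L], m), character(1))
      l2 <- vapply(ids, function(id) lab(id, revs[2L], m), character(1))
      ir[[m]] <- cohen_kappa(agree_table(l1, l2))
      per_cond_cohen[[m]] <- c(per_cond_cohen[[m]], ir[[m]]$kappa)
      counts <- cbind(case = (l1 == "case") + (l2 == "case"),
                      control = (l1 == "control") + (l2 == "control"))
      pooled_interrater[[m]] <- rbind(pooled_interrater[[m]], counts)
    }
    inter_strata[[cond]] <- rbind(
      chart = c(agree = ir$chart$n_agree,
                disagree = ir$chart$n - ir$chart$n_agree),
      keeper = c(agree = ir$keeper$n_agree,
                 disagree = ir$keeper$n - ir$keeper$n_agree))
    fisher_p[cond] <- fisher_exact(inter_strata[[cond]])

    # accuracy per method vs gold
    acc <- list()
    for (m in c("chart", "keeper")) {
      given <- c(vapply(ids, function(id) lab(id, revs[1L], m), character(1)),
                 vapply(ids, function(id) lab(id, revs[2L], m), character(1)))
      correct <- sum(given == gold_map[rep(ids, 2L)])
      acc[[m]] <- list(n = length(given), n_correct = correct,
                       percent = percent(correct, length(given)))
      pooled_acc[[m]] <- pooled_acc[[m]] +
        c(correct, length(given) - correct)
    }
    acc_strata[[cond]] <- rbind(
      chart = c(correct = acc$chart$n_correct,
                incorrect = acc$chart$n - acc$chart$n_correct),
      keeper = c(correct = acc$keeper$n_correct,
                 incorrect = acc$keeper$n - acc$keeper$n_correct))

    details[[cond]] <- list(intermethod = im, interrater = ir, accuracy = acc)
    rows[[cond]] <- data.frame(
      condition = cond,
      n_patients = length(ids),
      intermethod_n_agree = im$n_agree,
      intermethod_pct = im$percent,
      intermethod_kappa = im$kappa,
      interrater_chart_n_agree = ir$chart$n_agree,
      interrater_chart_pct = ir$chart$percent,
      interrater_chart_kappa = ir$chart$kappa,
      interrater_keeper_n_agree = ir$keeper$n_agree,
      interrater_keeper_pct = ir$keeper$percent,
      interrater_keeper_kappa = ir$keeper$kappa,
      accuracy_chart_pct = acc$chart$percent,
      accuracy_keeper_pct = acc$keeper$percent,
      fisher_p = fisher_p[[cond]])
  }

  # pooled row
  im_all <- cohen_kappa(pooled_intermethod)
  ir_all <- list()
  for (m in c("chart", "keeper")) {
    fl <- fleiss_kappa(pooled_interrater[[m]], raters_per_subject = 2L)
    kap <- if (fleiss_pooling == "pooled") fl$kappa
           else mean(per_cond_cohen[[m]])
    ir_all[[m]] <- list(fleiss = fl, kappa = kap,
                        n = fl$n, n_agree = fl$n_agree,
                        percent = percent(fl$n_agree, fl$n))
  }
  acc_all <- lapply(pooled_acc, function(v)
    list(n = sum(v), n_correct = v[1L], percent = percent(v[1L], sum(v))))

  # degenerate strata (e.g. perfect agreement under both methods) leave the
  # CMH comparison undefined rather than failing the whole report
  safe_cmh <- function(strata) {
    tryCatch(cmh_test(strata, correct = continuity_correction),
             error = function(e) list(statistic = NA_real_,
                                      p_value = NA_real_, df = 1L,
                                      n_strata_used = 0L))
  }
  cmh_interrater <- safe_cmh(inter_strata)
  cmh_accuracy <- safe_cmh(acc_strata)

  overall <- data.frame(
    condition = "Overall",
    n_patients = nrow(gold),
    intermethod_n_agree = im_all$n_agree,
    intermethod_pct = im_all$percent,
    intermethod_kappa = im_all$kappa,
    interrater_chart_n_agree = ir_all$chart$n_agree,
    interrater_chart_pct = ir_all$chart$percent,
    interrater_chart_kappa = ir_all$chart$kappa,
    interrater_keeper_n_agree = ir_all$keeper$n_agree,
    interrater_keeper_pct = ir_all$keeper$percent,
    interrater_keeper_kappa = ir_all$keeper$kappa,
    accuracy_chart_pct = acc_all$chart$percent,
    accuracy_keeper_pct = acc_all$keeper$percent,
    fisher_p = NA_real_)

  table <- rbind(do.call(rbind, rows), overall)
  rownames(table) <- NULL
  structure(list(
    table = table,
    comparisons = list(
      interrater_cmh = cmh_interrater,
      accuracy_cmh = cmh_accuracy,
      fisher_interrater = data.frame(condition = conditions,
                                     p_value = unname(fisher_p))),
    details = details,
    overall = list(intermethod = im_all, interrater = ir_all,
                   accuracy = acc_all),
    fleiss_pooling = fleiss_pooling),
    class = "keeper_evaluation")
}

#' @export
print.keeper_evaluation <- function(x, digits = 2, ...) {
  t <- x$table
  cat("Intermethod agreement, interrater agreement and accuracy\n")
  cat(sprintf("%-20s %14s %14s %14s %11s %11s\n", "",
              "Intermethod", "Interrater", "Interrater", "Accuracy",
              "Accuracy"))
  cat(sprintf("%-20s %14s %14s %14s %11s %11s\n", "Condition",
              "n (%) / kappa", "chart", "profile", "chart", "profile"))
  for (i in seq_len(nrow(t))) {
    cat(sprintf("%-20s %6d (%5.1f) %6d (%5.1f) %6d (%5.1f) %11.1f %11.1f\n",
                t$condition[i], t$intermethod_n_agree[i],
                t$intermethod_pct[i], t$interrater_chart_n_agree[i],
                t$interrater_chart_pct[i], t$interrater_keeper_n_agree[i],
                t$interrater_keeper_pct[i], t$accuracy_chart_pct[i],
                t$accuracy_keeper_pct[i]))
  }
  cat(sprintf("\nCMH interrater (chart vs profile): chi2 = %.3f, p = %.4f\n",
              x$comparisons$interrater_cmh$statistic,
              x$comparisons$interrater_cmh$p_value))
  cat(sprintf("CMH accuracy (chart vs profile):   chi2 = %.3f, p = %.4f\n",
              x$comparisons$accuracy_cmh$statistic,
              x$comparisons$accuracy_cmh$p_value))
  invisible(x)
}
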