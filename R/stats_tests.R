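# Hypothesis tests, questionnaire-order consistency, test-retest
# reliability (ICC) and subgroup analysis with Bonferroni correction.
#
# stats::t.test() refuses degenerate (zero-variance) data, which arises
# legitimately here, e.g. an all-maximizer simulation or the constant
# t = 10 comparator; safe_t_test() returns the limiting test instead
# (statistic 0 / p = 1 on an exact tie, +-Inf / p = 0 otherwise).

safe_t_test <- function(x, y = NULL, mu = 0, var.equal = TRUE,
                        paired = FALSE) {
  tt <- tryCatch(
    if (is.null(y)) stats::t.test(x, mu = mu)
    else stats::t.test(x, y, var.equal = var.equal, paired = paired),
    error = function(e) {
      if (!grepl("essentially constant", conditionMessage(e))) stop(e)
      d <- if (is.null(y)) mean(x) - mu else mean(x) - mean(y)
      list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
           p.value = if (d == 0) 1 else 0,
           estimate = if (is.null(y)) mean(x) else c(mean(x), mean(y)))
    })
  tt
}
# Following the analysis plan, all mean comparisons use Student's
# t-tests (equal variance); a paired variant is available for the
# within-respondent pairwise comparisons.

#' Test whether mean indifference departs from the maximizing count
#'
#' One-sample two-sided Student's t-test of the mean indifference count
#' against 10, the value a pure health-maximizer gives in every task.
#' Rejection means additional person-years do not carry constant social
#' value in this sample.
#'
#' @param p indifference counts for one task (extreme-preference
#'   respondents excluded).
#' @param mu maximizing reference value.
#' @param alpha significance level for the verdict.
#' @return list with `mean`, `statistic`, `p_value`, `reject`, `n`.
#' @export
test_h1 <- function(p, mu = 10, alpha = 0.05) {
  p <- p[!is.na(p)]
  if (length(p) < 2) stop("need at least 2 observations")
  tt <- safe_t_test(p, mu = mu)
  list(mean = unname(tt$estimate), statistic = unname(tt$statistic),
       p_value = tt$p.value, reject = tt$p.value < alpha, n = length(p))
}

#' Direction of a pairwise distributive comparison
#'
#' Programs are ordered so `P1 > P2` (program 1 has more, smaller
#' gains). Because total gains are equal, the mean indifference counts
#' stand in for the programs' social values: `mean_p1 < mean_p2` means
#' the fewer-beneficiary program is valued more (concentration, `"C"`);
#' `mean_p1 > mean_p2` means diffusion (`"D"`); exact ties give
#' `"none"`. When per-respondent data are supplied a two-sample
#' Student's t-test (or a paired t-test) is attached.
#'
#' @param prog1,prog2 lists/rows with `t`, `P`, `mean_p`.
#' @param data1,data2 optional vectors of per-respondent p values.
#' @param paired use a paired test (requires equal-length data).
#' @return one-row data frame (`t1`, `P1`, `mean_p1`, `t2`, `P2`,
#'   `mean_p2`, `direction`, `statistic`, `p_value`).
#' @export
pair_direction <- function(prog1, prog2, data1 = NULL, data2 = NULL,
                           paired = FALSE) {
  if (prog1$P == prog2$P) stop("programs must differ in beneficiary count P")
  if (prog1$P < prog2$P) {  # reorder so P1 > P2
    tmp <- prog1; prog1 <- prog2; prog2 <- tmp
    tmpd <- data1; data1 <- data2; data2 <- tmpd
  }
  direction <- if (prog1$mean_p < prog2$mean_p) "C"
               else if (prog1$mean_p > prog2$mean_p) "D" else "none"
  statistic <- p_value <- NA_real_
  if (!is.null(data1) && !is.null(data2)) {
    tt <- safe_t_test(data1, data2, paired = paired)
    statistic <- unname(tt$statistic); p_value <- tt$p.value
  }
  data.frame(t1 = prog1$t, P1 = prog1$P, mean_p1 = prog1$mean_p,
             t2 = prog2$t, P2 = prog2$P, mean_p2 = prog2$mean_p,
             direction = direction, statistic = statistic,
             p_value = p_value, stringsAsFactors = FALSE)
}

#' All pairwise distributive comparisons
#'
#' Builds every unordered pair among the supplied programs (typically
#' the five elicited tasks plus the virtual `t = 10` comparator, giving
#' 15 pairs), ordered within each pair by descending beneficiary count,
#' and labels each pair's direction via [pair_direction()].
#'
#' @param means data frame with columns `t`, `P`, `mean_p` (one row per
#'   program), e.g. from [mean_table()] plus [comparator_program()].
#' @param data optional named list of per-respondent p vectors, keyed by
#'   the program's `t` value as character; the comparator may be
#'   omitted, in which case a degenerate constant vector is used.
#' @param paired passed to [pair_direction()].
#' @return data frame of comparisons, one row per pair.
#' @examples
#' m <- rbind(data.frame(t = c(1, 2, 5, 20, 50), P = c(100, 50, 20, 5, 2),
#'                       mean_p = c(38.0, 17.4, 9.4, 32.2, 37.7)),
#'            comparator_program())
#' all_pairs(m)$direction
#' @export
all_pairs <- function(means, data = NULL, paired = FALSE) {
  means <- means[order(means$t), , drop = FALSE]
  n <- nrow(means)
  out <- list()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d1 <- d2 <- NULL
    if (!is.null(data)) {
      get_data <- function(k) {
        key <- as.character(means$t[k])
        if (!is.null(data[[key]])) data[[key]]
        else rep(means$mean_p[k], max(lengths(data)))
      }
      d1 <- get_data(i); d2 <- get_data(j)
    }
    out[[length(out) + 1L]] <- pair_direction(
      means[i, ], means[j, ], d1, d2, paired = paired)
  }
  res <- do.call(rbind, out)
  res$pair <- seq_len(nrow(res))
  res[, c("pair", setdiff(names(res), "pair"))]
}

#' Starting-point (version-order) consistency test
#'
#' Per task, a two-sided equal-variance Student's t-test of the mean
#' indifference count between the ascending and descending
#' questionnaire versions.
#'
#' @param responses long response data frame with a `version` column.
#' @param tasks task table.
#' @return data frame: `task_id`, per-version means and n, `statistic`,
#'   `p_value`.
#' @export
version_consistency <- function(responses, tasks = pto_tasks()) {
  if (length(unique(responses$version)) < 2)
    stop("both questionnaire versions must be present")
  do.call(rbind, lapply(tasks$task_id, function(id) {
    r <- responses[responses$task_id == id & !is.na(responses$p), ]
    x <- r$p[r$version == "ascending"]
    y <- r$p[r$version == "descending"]
    tt <- safe_t_test(x, y)
    data.frame(task_id = id, mean_ascending = mean(x), n_ascending = length(x),
               mean_descending = mean(y), n_descending = length(y),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
}

#' Intraclass correlation, two-way absolute agreement, single measure
#'
#' ICC(A,1) in the McGraw & Wong nomenclature: subjects and occasions
#' are crossed, agreement is absolute, one measurement per cell.
#' Computed from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param x1,x2 paired measurements (round 1 and round 2).
#' @return the coefficient (1 = perfect agreement; ~0 = none).
#' @export
icc_agreement <- function(x1, x2) {
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1); k <- 2
  if (n < 2) stop("need at least 2 matched pairs")
  m <- cbind(x1, x2)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Test-retest reliability of the PTO battery
#'
#' Matches respondents across the two survey rounds and reports the
#' ICC(A,1) per task plus the mean across tasks.
#'
#' @param round1,round2 long response data frames.
#' @param tasks task table.
#' @return list with `per_task` (data frame `task_id`, `icc`, `n_pairs`)
#'   and `mean_icc`.
#' @export
icc_test_retest <- function(round1, round2, tasks = pto_tasks()) {
  per_task <- do.call(rbind, lapply(tasks$task_id, function(id) {
    r1 <- round1[round1$task_id == id, c("respondent_id", "p")]
    r2 <- round2[round2$task_id == id, c("respondent_id", "p")]
    m <- merge(r1, r2, by = "respondent_id", suffixes = c("_1", "_2"))
    m <- m[!is.na(m$p_1) & !is.na(m$p_2), ]
    data.frame(task_id = id, icc = icc_agreement(m$p_1, m$p_2),
               n_pairs = nrow(m), stringsAsFactors = FALSE)
  }))
  list(per_task = per_task, mean_icc = mean(per_task$icc, na.rm = TRUE))
}

#' Subgroup analysis of distributive preferences
#'
#' For each level of a demographic grouping variable: per-task mean
#' indifference counts compared with the total population by
#' equal-variance Student's t-tests, with Bonferroni correction over
#' the whole family (subgroups x tasks) within the grouping variable;
#' and a subgroup SWF threshold via [pto_swf()] (skipped with a notice
#' for subgroups of fewer than `min_n` respondents).
#'
#' @param responses long response data frame (round 1, trade-off
#'   respondents; extremes are excluded internally for the means).
#' @param profiles population data frame with demographics.
#' @param group name of the grouping column in `profiles`.
#' @param tasks task table.
#' @param alpha family significance level.
#' @param min_n minimum subgroup size for a threshold fit.
#' @return list with `comparisons` (data frame with `group`, `task_id`,
#'   means, `statistic`, `p_value`, `p_bonferroni`, `significant`) and
#'   `thresholds` (per subgroup, `NA` + notice when skipped).
#' @export
subgroup_analysis <- function(responses, profiles, group,
                              tasks = pto_tasks(), alpha = 0.05,
                              min_n = 10) {
  if (!group %in% names(profiles))
    stop("grouping variable '", group, "' not found in profiles")
  flags <- flag_nontradeoff(responses, tasks)
  keep <- names(flags)[!flags]
  responses <- responses[responses$respondent_id %in% keep, , drop = FALSE]
  levs <- sort(unique(as.character(profiles[[group]])))
  m <- length(levs) * nrow(tasks)
  comp <- list(); thr <- list()
  for (g in levs) {
    ids <- profiles$respondent_id[as.character(profiles[[group]]) == g]
    sub <- responses[responses$respondent_id %in% ids, , drop = FALSE]
    for (id in tasks$task_id) {
      x <- sub$p[sub$task_id == id]
      y <- responses$p[responses$task_id == id]
      row <- data.frame(group = g, task_id = id, n = length(x),
                        mean_subgroup = NA_real_, mean_total = mean(y),
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
      if (length(x) >= 2) {
        tt <- safe_t_test(x, y)
        row$mean_subgroup <- mean(x)
        row$statistic <- unname(tt$statistic)
        row$p_value <- tt$p.value
      }
      comp[[length(comp) + 1L]] <- row
    }
    n_sub <- length(unique(sub$respondent_id))
    thr[[g]] <- if (n_sub >= min_n) {
      fit <- pto_swf(sub, tasks, exclude_extremes = FALSE)
      data.frame(group = g, n = n_sub, threshold = fit$threshold,
                 note = "", stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, n = n_sub, threshold = NA_real_,
                 note = sprintf("skipped: fewer than %d respondents", min_n),
                 stringsAsFactors = FALSE)
    }
  }
  comp <- do.call(rbind, comp)
  comp$p_bonferroni <- pmin(1, comp$p_value * m)
  comp$significant <- !is.na(comp$p_bonferroni) & comp$p_bonferroni < alpha
  list(comparisons = comp, thresholds = do.call(rbind, thr),
       m_comparisons = m)
}
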