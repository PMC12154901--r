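# End-to-end orchestration: simulate -> elicit -> classify -> exclude ->
# fit + bootstrap -> tests -> report files. A config plus a seed fully
# determines every output.

#' Study run configuration
#'
#' @param population a [pto_population_config()].
#' @param bootstrap bootstrap replications for the threshold CI.
#' @param seed master seed; all randomness derives from it.
#' @param subgroup_vars demographic columns to analyse as subgroups.
#' @param second_round run the retest round on a subsample.
#' @return list of class `pto_config`.
#' @export
pto_config <- function(population = pto_population_config(),
                       bootstrap = 1000, seed = 1,
                       subgroup_vars = c("income", "health", "age_band",
                                         "education"),
                       second_round = TRUE) {
  structure(list(population = population, bootstrap = bootstrap,
                 seed = as.integer(seed), subgroup_vars = subgroup_vars,
                 second_round = second_round),
            class = "pto_config")
}

#' Per-task mean indifference table
#'
#' The mean (and SD) indifference count per task, by questionnaire
#' version and overall, with the version-difference test and the
#' one-sample test against the maximizing count 10, computed over
#' trade-off respondents only.
#'
#' @param responses long response data frame (round 1).
#' @param tasks task table.
#' @param exclude_extremes drop non-trade-off respondents first.
#' @return data frame, one row per task, including columns `t`, `P`,
#'   `mean_p`, `sd_p`, per-version means, and the two test p-values.
#' @export
mean_table <- function(responses, tasks = pto_tasks(),
                       exclude_extremes = TRUE) {
  if (exclude_extremes) {
    flags <- flag_nontradeoff(responses, tasks)
    responses <- responses[responses$respondent_id %in%
                             names(flags)[!flags], , drop = FALSE]
  }
  vc <- version_consistency(responses, tasks)
  do.call(rbind, lapply(seq_len(nrow(tasks)), function(i) {
    id <- tasks$task_id[i]
    p <- responses$p[responses$task_id == id]
    h1 <- test_h1(p)
    data.frame(task_id = id, t = tasks$t[i], P = tasks$P[i], T = tasks$T[i],
               n = length(p), mean_p = mean(p), sd_p = stats::sd(p),
               mean_ascending = vc$mean_ascending[vc$task_id == id],
               mean_descending = vc$mean_descending[vc$task_id == id],
               p_version = vc$p_value[vc$task_id == id],
               p_vs_10 = h1$p_value, stringsAsFactors = FALSE)
  }))
}

#' Run the full simulated PTO study
#'
#' Draws a population, assigns questionnaire versions at random
#' (50/50), elicits the five-task battery, classifies preference types,
#' excludes non-trade-off respondents, fits the social welfare function
#' with a bootstrap CI for the threshold, runs the hypothesis tests,
#' version-consistency tests, the retest round with ICCs, and the
#' subgroup analyses.
#'
#' @param config a [pto_config()].
#' @param tasks task table.
#' @return list of class `pto_study` with all stage outputs.
#' @examples
#' \donttest{
#' study <- run_pto_study(pto_config(population = pto_population_config(n = 80),
#'                                   bootstrap = 50, seed = 7))
#' print(study)
#' }
#' @export
run_pto_study <- function(config = pto_config(), tasks = pto_tasks()) {
  set.seed(config$seed)
  profiles <- sample_population(config$population)
  profiles$version <- sample(c("ascending", "descending"),
                             nrow(profiles), replace = TRUE)
  responses <- elicit_population(profiles, tasks)

  labels <- flag_nontradeoff(responses, tasks)
  distribution <- type_distribution(responses, tasks)
  means <- mean_table(responses, tasks)

  keep <- names(labels)[!labels]
  included <- responses[responses$respondent_id %in% keep, , drop = FALSE]
  fit <- pto_swf(included, tasks, exclude_extremes = FALSE,
                 bootstrap = config$bootstrap, t_max = 60)

  h1 <- lapply(stats::setNames(tasks$task_id, tasks$task_id), function(id)
    test_h1(included$p[included$task_id == id]))
  prog_means <- rbind(
    data.frame(t = means$t, P = means$P, mean_p = means$mean_p),
    comparator_program())
  pdata <- stats::setNames(
    lapply(tasks$task_id, function(id) included$p[included$task_id == id]),
    as.character(tasks$t))
  pairs <- all_pairs(prog_means, data = pdata)
  versions <- version_consistency(included, tasks)

  round2 <- icc <- NULL
  if (isTRUE(config$second_round)) {
    round2 <- second_round(profiles, config$population, tasks)
    icc <- icc_test_retest(responses, round2, tasks)
  }
  subgroups <- lapply(
    stats::setNames(config$subgroup_vars, config$subgroup_vars),
    function(v) subgroup_analysis(responses, profiles, v, tasks))

  structure(list(
    config = config, tasks = tasks, profiles = profiles,
    responses = responses, round2 = round2,
    nontradeoff = labels, distribution = distribution,
    mean_table = means, fit = fit, h1 = h1, pairs = pairs,
    version_tests = versions, icc = icc, subgroups = subgroups,
    n_excluded = sum(labels)), class = "pto_study")
}

#' @export
print.pto_study <- function(x, ...) {
  cat(sprintf("Simulated PTO study: %d respondents, %d excluded as non-trade-off\n",
              nrow(x$profiles), x$n_excluded))
  cat("\nPreference type distribution (% per task):\n")
  print(round(x$distribution, 1))
  cat("\nMean indifference counts (trade-off respondents):\n")
  print(round(x$mean_table[, c("t", "P", "n", "mean_p", "sd_p", "p_vs_10")], 3),
        row.names = FALSE)
  cat("\n")
  print(x$fit)
  if (!is.null(x$icc)) {
    cat("\nTest-retest ICC per task:\n")
    print(round(stats::setNames(x$icc$per_task$icc, x$icc$per_task$task_id), 3))
  }
  invisible(x)
}

#' Machine-readable study summary
#'
#' Flattens the headline results of a study run into a plain list,
#' suitable for JSON serialization; the same config and seed always
#' produce a byte-identical summary file.
#'
#' @param study a `pto_study`.
#' @return a named list.
#' @export
study_summary <- function(study) {
  list(
    seed = study$config$seed,
    n = nrow(study$profiles),
    n_excluded = study$n_excluded,
    distribution = as.data.frame.table(study$distribution,
                                       responseName = "percent"),
    mean_p = stats::setNames(study$mean_table$mean_p, study$mean_table$task_id),
    coefficients = as.list(coef(study$fit)),
    r2_adj = study$fit$r2_adj,
    threshold = study$fit$threshold,
    threshold_ci = study$fit$ci,
    pair_directions = stats::setNames(study$pairs$direction, study$pairs$pair),
    mean_icc = if (!is.null(study$icc)) study$icc$mean_icc else NULL
  )
}

#' Write the study's report bundle
#'
#' Emits the tabular artifacts of a run as plain-text files in `dir`:
#' the task battery (`tasks.csv`), responses, the preference-type
#' distribution, the mean table, the pairwise comparisons, the fit
#' coefficients, per-subgroup comparisons, and `summary.json`.
#'
#' @param study a `pto_study`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(as.data.frame(study$tasks), "tasks.csv")
  write_responses(study$responses, file.path(dir, "responses.csv"))
  dist <- data.frame(category = rownames(study$distribution),
                     study$distribution, check.names = FALSE)
  w(dist, "type_distribution.csv")
  w(study$mean_table, "mean_table.csv")
  w(study$pairs, "pairwise_comparisons.csv")
  co <- summary(study$fit)$coefficients
  w(data.frame(term = rownames(co), co, check.names = FALSE), "swf_fit.csv")
  for (v in names(study$subgroups))
    w(study$subgroups[[v]]$comparisons, sprintf("subgroup_%s.csv", v))
  jsonlite::write_json(study_summary(study), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Read / write long-format response files
#'
#' Responses travel as delimited text with columns `respondent_id`,
#' `version`, `task_id`, `round`, `p` (and optionally `n_questions`,
#' `excluded_gate`). Reading validates bounds against the task table
#' and rejects duplicate respondent x task x round keys with row-level
#' messages.
#'
#' @param path file path.
#' @param tasks task table used for validation.
#' @return `read_responses` returns the validated data frame.
#' @export
read_responses <- function(path, tasks = pto_tasks()) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("respondent_id", "version", "task_id", "round", "p")
  miss <- setdiff(needed, names(r))
  if (length(miss))
    stop("response file is missing columns: ", paste(miss, collapse = ", "))
  i <- match(r$task_id, tasks$task_id)
  if (anyNA(i)) {
    bad <- which(is.na(i))[1]
    stop(sprintf("row %d: unknown task_id '%s'", bad, r$task_id[bad]))
  }
  oob <- which(!is.na(r$p) &
                 (r$p < tasks$answer_lower[i] | r$p > tasks$answer_upper[i]))
  if (length(oob))
    stop(sprintf("row %d: p = %s outside bounds [%d, %d] for task %s",
                 oob[1], format(r$p[oob[1]]), tasks$answer_lower[i[oob[1]]],
                 tasks$answer_upper[i[oob[1]]], r$task_id[oob[1]]))
  key <- paste(r$respondent_id, r$task_id, r$round)
  if (anyDuplicated(key))
    stop("duplicate respondent x task x round keys, first at row ",
         which(duplicated(key))[1])
  r
}

#' @rdname read_responses
#' @param responses a response data frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}
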