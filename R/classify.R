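# Five-category distributive-preference taxonomy. With pbar = P*t/T the
# maximizing indifference count:
#   maximizing              p == pbar
#   concentration           p < pbar when t < T;  p > pbar when t > T
#   diffusion               p > pbar when t < T;  p < pbar when t > T
#   extreme egalitarianism  p at the bound favouring beneficiary count
#   extreme inequality      p at the bound favouring gain size
# Bound checks take precedence over the interior rules.

PREF_CATEGORIES <- c("concentration", "diffusion", "maximizing",
                     "extreme_egalitarianism", "extreme_inequality_seeking")

#' Classify an indifference count into a distributive-preference type
#'
#' @param task a one-row task.
#' @param p indifference count(s) within the task's answer bounds.
#' @return factor with levels `r paste(PREF_CATEGORIES, collapse=", ")`.
#' @examples
#' t1 <- task_by_id(pto_tasks(), "t1")
#' classify_response(t1, c(38, 10, 3, 100, 1))
#' @export
classify_response <- function(task, p) {
  if (any(p < task$answer_lower | p > task$answer_upper, na.rm = TRUE))
    stop("p outside answer bounds for task ", task$task_id)
  small <- task$t < task$T
  pbar <- task$P * task$t / task$T
  upper_cat <- if (small) "extreme_egalitarianism" else "extreme_inequality_seeking"
  lower_cat <- if (small) "extreme_inequality_seeking" else "extreme_egalitarianism"
  out <- ifelse(p == task$answer_upper, upper_cat,
         ifelse(p == task$answer_lower, lower_cat,
         ifelse(p == pbar, "maximizing",
         ifelse(xor(p < pbar, !small), "concentration", "diffusion"))))
  factor(out, levels = PREF_CATEGORIES)
}

#' Flag respondents who never traded off
#'
#' A respondent whose answer sits at an answer bound in any task is
#' indistinguishable from one refusing to trade beneficiaries against
#' gain size; such respondents are flagged and excluded from mean
#' comparisons and the social-welfare-function fit.
#'
#' @param responses long response data frame (one round).
#' @param tasks task table.
#' @return named logical vector over respondent ids (`TRUE` = flagged);
#'   gate-excluded or incomplete respondents are also flagged.
#' @export
flag_nontradeoff <- function(responses, tasks = pto_tasks()) {
  resp <- split(responses, responses$respondent_id)
  vapply(resp, function(r) {
    if (nrow(r) < nrow(tasks) || any(is.na(r$p))) return(TRUE)
    any(vapply(seq_len(nrow(r)), function(i) {
      task <- task_by_id(tasks, r$task_id[i])
      as.character(classify_response(task, r$p[i])) %in%
        c("extreme_egalitarianism", "extreme_inequality_seeking")
    }, logical(1)))
  }, logical(1))
}

#' Per-task distribution of preference types
#'
#' @param responses long response data frame (one round).
#' @param tasks task table.
#' @return matrix (categories x tasks) of percentages; columns sum
#'   to 100 over classified responses.
#' @export
type_distribution <- function(responses, tasks = pto_tasks()) {
  out <- sapply(tasks$task_id, function(id) {
    task <- task_by_id(tasks, id)
    p <- responses$p[responses$task_id == id & !is.na(responses$p)]
    if (!length(p)) return(stats::setNames(rep(NA_real_, length(PREF_CATEGORIES)),
                                           PREF_CATEGORIES))
    100 * table(classify_response(task, p)) / length(p)
  })
  out <- matrix(out, nrow = length(PREF_CATEGORIES),
                dimnames = list(PREF_CATEGORIES, tasks$task_id))
  out
}

#' Concentration-to-diffusion ratio for one task
#'
#' The concentration share divided by the diffusion share, computed
#' from unrounded shares (rounding is left for display).
#'
#' @param distribution a distribution matrix from [type_distribution()],
#'   or a numeric vector of category percentages named like its rows.
#' @param task_id task column to use (ignored for a vector input).
#' @return the ratio (numeric scalar).
#' @examples
#' concentration_diffusion_ratio(c(concentration = 7.2, diffusion = 89))
#' @export
concentration_diffusion_ratio <- function(distribution, task_id = NULL) {
  shares <- if (is.matrix(distribution)) distribution[, task_id] else distribution
  conc <- shares[["concentration"]]
  diff <- shares[["diffusion"]]
  if (is.na(diff) || diff == 0)
    stop("diffusion share is zero; ratio undefined")
  conc / diff
}
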