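#' The five-task person trade-off battery
#'
#' Builds the standard PTO task set. Each task asks how many patients
#' `p`, each gaining `T = 10` years in full health under program B, make
#' program B as good as program A, in which `P` patients each gain `t`
#' years. The individual gain `t` takes the values 1, 2, 5, 20 and 50
#' years while the total gain is held fixed at `P * t = 100` person-years,
#' so the battery isolates the effect of gain size on distributive
#' preferences.
#'
#' `answer_lower`/`answer_upper` are the bounds of the range a respondent
#' can express. For the small-gain tasks (`t < T`) the upper bound is `P`
#' (program B can at most treat as many people as are shown in the first,
#' equal-numbers choice) and the lower bound is 1. For the large-gain
#' tasks (`t > T`) answers run from `P` (the bisection bracket can never
#' fall below the equal-numbers starting point) up to 200, the top of the
#' bounded open-ended range.
#'
#' @return A data frame of class `pto_tasks` with columns `task_id`, `t`,
#'   `P`, `T`, `answer_lower`, `answer_upper`; one row per task.
#' @examples
#' tasks <- pto_tasks()
#' all(tasks$P * tasks$t == 100)
#' @export
pto_tasks <- function() {
  tasks <- data.frame(
    task_id = c("t1", "t2", "t5", "t20", "t50"),
    t = c(1, 2, 5, 20, 50),
    P = c(100, 50, 20, 5, 2),
    T = rep(10, 5),
    answer_lower = c(1, 1, 1, 5, 2),
    answer_upper = c(100, 50, 20, 200, 200),
    stringsAsFactors = FALSE
  )
  class(tasks) <- c("pto_tasks", "data.frame")
  validate_tasks(tasks)
  tasks
}

#' Validate a PTO task table
#'
#' Checks the structural invariants any task battery must satisfy:
#' positive gains, whole-person counts, and coherent answer bounds.
#'
#' @param tasks a data frame shaped like [pto_tasks()].
#' @return `tasks`, invisibly, if valid; otherwise an error.
#' @export
validate_tasks <- function(tasks) {
  needed <- c("task_id", "t", "P", "T", "answer_lower", "answer_upper")
  miss <- setdiff(needed, names(tasks))
  if (length(miss))
    stop("task table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tasks$task_id))
    stop("duplicate task_id in task table")
  with(tasks, {
    if (any(t <= 0) || any(T <= 0)) stop("gains t and T must be positive")
    if (any(P < 1) || any(P != round(P))) stop("P must be a whole count >= 1")
    if (any(answer_lower < 1)) stop("answer_lower must be >= 1")
    if (any(answer_upper <= answer_lower)) stop("answer_upper must exceed answer_lower")
  })
  invisible(tasks)
}

#' Look up one task by id
#'
#' @param tasks a task table from [pto_tasks()].
#' @param task_id a single task id.
#' @return the matching one-row data frame.
#' @export
task_by_id <- function(tasks, task_id) {
  i <- match(task_id, tasks$task_id)
  if (is.na(i)) stop("unknown task_id: ", task_id)
  tasks[i, , drop = FALSE]
}

#' Indifference count of a pure health-maximizer
#'
#' A respondent who cares only about total person-years is indifferent
#' when `p * T = P * t`, i.e. at `p = P * t / T`. For the standard battery
#' this is 10 in every task (100 person-years on both sides).
#'
#' @param task one or more rows of a task table.
#' @return integer vector of maximizing indifference counts.
#' @examples
#' maximizing_indifference(pto_tasks())   # 10 10 10 10 10
#' @export
maximizing_indifference <- function(task) {
  p <- task$P * task$t / task$T
  bad <- abs(p - round(p)) > 1e-9
  if (any(bad))
    stop("maximizing indifference is not a whole count for task(s): ",
         paste(task$task_id[bad], collapse = ", "))
  round(p)
}

#' Task order for a questionnaire version
#'
#' Version `"ascending"` presents the tasks in order of increasing
#' individual gain t (1, 2, 5, 20, 50 years); `"descending"` presents
#' the reverse. Two orders are used to control for starting-point bias.
#'
#' @param version `"ascending"` or `"descending"`.
#' @param tasks a task table.
#' @return the task table reordered for presentation.
#' @export
task_sequence <- function(version = c("ascending", "descending"),
                          tasks = pto_tasks()) {
  version <- match.arg(version)
  ord <- order(tasks$t)
  if (version == "descending") ord <- rev(ord)
  out <- tasks[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The virtual comparator program (t = 10)
#'
#' Program B itself, viewed as a program: 10 patients each gaining 10
#' years. It is never elicited (it would compare a program with itself)
#' but enters the pairwise preference comparisons with indifference
#' count fixed at 10.
#'
#' @return a one-row data frame with `t`, `P` and `mean_p`.
#' @export
comparator_program <- function() {
  data.frame(t = 10, P = 10, mean_p = 10)
}

#' Serialize / read a task table as JSON
#'
#' @param tasks a task table.
#' @param path file path.
#' @return `read_tasks_json` returns a validated `pto_tasks` data frame.
#' @export
write_tasks_json <- function(tasks, path) {
  validate_tasks(tasks)
  jsonlite::write_json(as.data.frame(tasks), path, digits = NA)
  invisible(path)
}

#' @rdname write_tasks_json
#' @export
read_tasks_json <- function(path) {
  tasks <- jsonlite::fromJSON(path)
  tasks <- as.data.frame(tasks, stringsAsFactors = FALSE)
  class(tasks) <- c("pto_tasks", "data.frame")
  validate_tasks(tasks)
  tasks
}
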