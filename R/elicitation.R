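# Three-step adaptive PTO elicitation:
#   1. rationality gate: equal-numbers choice; the program with larger
#      per-person gains should be preferred, otherwise re-ask once.
#   2. bisection ladder on the number of program-B beneficiaries; the
#      first follow-up halves the previous count, later probes take the
#      bracket midpoint (nearest integer, ties up); stops when the
#      bracket width is <= 5.
#   3. bounded open-ended finish: a drop-down over the integers still
#      consistent with the expressed choices.
# Under forced choice every answer expresses only weak preference, so
# both bracket endpoints stay in the final option list; the list is
# clipped to the task's global answer bounds.

WIDTH_STOP <- 5

#' First question of a PTO task
#'
#' The opening pairwise choice shows equal numbers of beneficiaries in
#' both programs (`n_A = n_B = P`); only the per-person gains differ.
#'
#' @param task a one-row task.
#' @return list with `n_A`, `n_B`, `task_id`, `step_index`.
#' @export
initial_choice <- function(task) {
  list(n_A = task$P, n_B = task$P, task_id = task$task_id, step_index = 1L)
}

#' Rationality gate on the equal-numbers choice
#'
#' With equal beneficiary counts, the program with the larger per-person
#' gain dominates; choosing the other program is flagged as unexpected
#' (the questioning is paused and the choice re-asked once).
#'
#' @param task a one-row task.
#' @param choice1_answer `"A"` or `"B"`.
#' @return `"pass"` or `"flag"`.
#' @export
rationality_gate <- function(task, choice1_answer) {
  expected <- if (task$t < task$T) "B" else "A"
  if (identical(choice1_answer, expected)) "pass" else "flag"
}

# bracket midpoint: nearest integer, ties rounding up
bisect_mid <- function(lower, upper) {
  (lower + upper) %/% 2 + (lower + upper) %% 2
}

#' Drop-down options for a terminal indifference interval
#'
#' All integers from `lower` to `upper` that lie within the task's
#' global answer bounds. Both endpoints are offered: a forced choice at
#' an endpoint expresses only weak preference, so the endpoint remains a
#' consistent indifference answer. The global bounds keep the extreme
#' categories expressible.
#'
#' @param lower,upper terminal bracket on the program-B count.
#' @param task a one-row task.
#' @return increasing integer vector of admissible answers.
#' @export
terminal_options <- function(lower, upper, task) {
  lo <- max(lower, task$answer_lower)
  hi <- min(upper, task$answer_upper)
  if (hi < lo) stop("empty terminal option list for task ", task$task_id)
  seq.int(lo, hi)
}

#' Answer policies for the elicitation engine
#'
#' A policy stands in for a respondent: `choose(n_A, n_B, task)` returns
#' `"A"` or `"B"` for a pairwise choice and `fill_in(options, task)`
#' picks one member of the terminal option list.
#'
#' `threshold_policy(q)` is the deterministic comparator used as the
#' engine's consistency oracle: it prefers B strictly when `n_B > q`
#' (ties go to A) and fills in the option nearest `q`.
#'
#' @param q latent indifference count (may be non-integer).
#' @return a policy (list of two functions).
#' @export
threshold_policy <- function(q) {
  list(
    choose = function(n_A, n_B, task) {
      # equal-numbers gate: decided by per-person gain, like any
      # respondent who passes the rationality check
      if (n_B == n_A) return(if (task$T > task$t) "B" else "A")
      if (n_B > q) "B" else "A"
    },
    fill_in = function(options, task) {
      options[which.min(abs(options - q))]
    }
  )
}

#' Run one PTO task against an answer policy
#'
#' Drives the three-step procedure to completion and records the full
#' question trace. For small-gain tasks (`t < T`) the ladder bisects
#' downward from `P`; for large-gain tasks (`t > T`) the second question
#' jumps to 100 beneficiaries, and if program A is still preferred the
#' answer is taken open-ended on 100-200.
#'
#' @param task a one-row task.
#' @param policy an answer policy, e.g. [threshold_policy()].
#' @return list with elements `p` (indifference count, `NA` if excluded
#'   at the gate), `excluded_gate`, `n_questions`, `options` (terminal
#'   list) and `trace` (data frame of questions, answers and brackets).
#' @examples
#' task1 <- task_by_id(pto_tasks(), "t1")
#' run_elicitation(task1, threshold_policy(10))$p   # 10
#' @export
run_elicitation <- function(task, policy) {
  t <- task$t; T <- task$T; P <- task$P
  max_q <- 2L + ceiling(log2(task$answer_upper)) + 3L
  trace <- list()
  nq <- 0L
  ask <- function(n_B, lower, upper) {
    nq <<- nq + 1L
    if (nq > max_q) stop("elicitation failed to terminate for task ", task$task_id)
    ans <- policy$choose(n_A = P, n_B = n_B, task = task)
    if (!ans %in% c("A", "B"))
      stop("policy returned invalid choice '", ans, "'")
    trace[[length(trace) + 1L]] <<- data.frame(
      step = nq, n_A = P, n_B = n_B, choice = ans,
      lower = lower, upper = upper, stringsAsFactors = FALSE)
    ans
  }
  done <- function(p, lower, upper, options, excluded = FALSE) {
    tr <- do.call(rbind, trace)
    list(p = p, excluded_gate = excluded, n_questions = nq,
         options = options, lower = lower, upper = upper, trace = tr)
  }

  # step 1: rationality gate (re-ask once on an unexpected answer)
  ans1 <- ask(P, NA, NA)
  if (rationality_gate(task, ans1) == "flag") {
    ans1 <- ask(P, NA, NA)
    if (rationality_gate(task, ans1) == "flag")
      return(done(NA_real_, NA, NA, NULL, excluded = TRUE))
  }

  if (t < T) {
    # B preferred at n_B = P, so p <= P; bisect downward from P
    lower <- 0; upper <- P
  } else {
    # A preferred at n_B = P, so p >= P; jump to 100
    lower <- P; upper <- task$answer_upper
    ans <- ask(100, lower, upper)
    if (ans == "A") {
      # prefers A even with 100 beneficiaries: open-ended on 100-200
      lower <- 100
      opts <- terminal_options(lower, upper, task)
      p <- pick_fill_in(policy, opts, task)
      return(done(p, lower, upper, opts))
    }
    upper <- 100
    # first follow-up halves the previous count (100 -> 50)
    if (upper - lower > WIDTH_STOP) {
      ans <- ask(50, lower, upper)
      if (ans == "B") upper <- 50 else lower <- 50
    }
  }

  while (upper - lower > WIDTH_STOP) {
    nb <- bisect_mid(lower, upper)
    ans <- ask(nb, lower, upper)
    if (ans == "B") upper <- nb else lower <- nb
  }
  opts <- terminal_options(lower, upper, task)
  p <- pick_fill_in(policy, opts, task)
  done(p, lower, upper, opts)
}

pick_fill_in <- function(policy, options, task) {
  p <- policy$fill_in(options, task)
  if (length(p) != 1L || !p %in% options)
    stop("policy fill-in returned a value outside the offered options")
  as.numeric(p)
}

#' Replay a stored elicitation trace
#'
#' Re-runs the engine feeding back the recorded choices (and the stored
#' fill-in answer), reproducing the indifference count exactly. Useful
#' for auditing stored response files.
#'
#' @param task a one-row task.
#' @param trace a trace data frame from [run_elicitation()].
#' @param p the recorded indifference count (the terminal fill-in).
#' @return the replayed result, as from [run_elicitation()].
#' @export
replay_trace <- function(task, trace, p) {
  i <- 0L
  policy <- list(
    choose = function(n_A, n_B, task) {
      i <<- i + 1L
      if (i > nrow(trace) || trace$n_B[i] != n_B)
        stop("trace does not match the engine's question sequence")
      trace$choice[i]
    },
    fill_in = function(options, task) p
  )
  run_elicitation(task, policy)
}
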