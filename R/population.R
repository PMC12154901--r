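# Synthetic respondent populations. Each respondent carries a latent
# social-value curve u_i(t) = 10 * exp(beta*(t-10)) * (t/10)^gamma
# (normalized so u_i(10) = 10), a behavioural archetype, and a logistic
# choice-noise scale acting on the log of total program values.

ARCHETYPES <- c("parametric", "maximizer", "extreme_egalitarian",
                "extreme_inequality", "non_trader")

#' Latent social value of a health gain
#'
#' Evaluates a respondent's latent curve
#' `u(t) = 10 * exp(beta*(t-10)) * (t/10)^gamma`, normalized so that
#' `u(10) = 10` (the comparator program's gain). `beta` is the
#' exponential trend per year (sign free); `gamma > 0` is the power
#' coefficient; `beta = 0, gamma = 1` is the health-maximizer's linear
#' curve `u(t) = t`.
#'
#' @param beta exponential-trend coefficient per year.
#' @param gamma power coefficient (> 0).
#' @param t health gain in years (> 0); vectorized.
#' @return social value(s) on the comparator scale.
#' @examples
#' latent_social_value(0, 1, 7)           # 7
#' latent_social_value(0.035, 0.646, 1)   # about 1.649
#' @export
latent_social_value <- function(beta, gamma, t) {
  if (any(t <= 0)) stop("t must be positive")
  10 * exp(beta * (t - 10)) * (t / 10)^gamma
}

#' Latent indifference count for a task
#'
#' Under a constant social value of additional beneficiaries, program B
#' with `p` patients matches program A when `p * u(T) = P * u(t)`, i.e.
#' `p* = P * u(t) / 10`. The result may be non-integer and is clipped to
#' the task's answer bounds.
#'
#' @param beta,gamma latent curve parameters.
#' @param task one or more task rows.
#' @return real-valued indifference count(s), clipped to bounds.
#' @export
latent_indifference <- function(beta, gamma, task) {
  p <- task$P * latent_social_value(beta, gamma, task$t) / 10
  pmin(pmax(p, task$answer_lower), task$answer_upper)
}

#' Build an answer policy from latent preferences
#'
#' Bridges a simulated respondent to the elicitation engine.
#' Parametric respondents choose B with probability
#' `plogis((log(n_B * T) - log(n_A * u(t))) / noise_scale)` (deterministic
#' comparison, ties to A, when `noise_scale = 0`) and fill in the option
#' nearest their latent indifference count. Maximizers compare total
#' person-years. The extreme archetypes are lexicographic: extreme
#' egalitarians always prefer the program treating more people (ties by
#' larger per-person gain), extreme inequality-seekers always prefer the
#' larger per-person gain. Non-traders behave like one of the two
#' extremes according to their `side`.
#'
#' @param archetype one of `r paste(ARCHETYPES, collapse=", ")`.
#' @param beta,gamma,noise_scale parametric curve and noise parameters.
#' @param side for non-traders: `"people"` or `"gains"`.
#' @return an answer policy for [run_elicitation()].
#' @export
make_policy <- function(archetype = "parametric", beta = 0, gamma = 1,
                        noise_scale = 0, side = "people") {
  archetype <- match.arg(archetype, ARCHETYPES)
  if (archetype == "non_trader")
    archetype <- if (side == "people") "extreme_egalitarian" else "extreme_inequality"
  if (archetype == "maximizer") { beta <- 0; gamma <- 1; noise_scale <- 0 }
  if (archetype %in% c("parametric", "maximizer")) {
    list(
      choose = function(n_A, n_B, task) {
        d <- log(n_B * task$T) - log(n_A * latent_social_value(beta, gamma, task$t))
        if (noise_scale > 0) {
          if (stats::runif(1) < stats::plogis(d / noise_scale)) "B" else "A"
        } else if (d > 0) "B" else "A"
      },
      fill_in = function(options, task) {
        q <- latent_indifference(beta, gamma, task)
        options[which.min(abs(options - q))]
      }
    )
  } else if (archetype == "extreme_egalitarian") {
    list(
      choose = function(n_A, n_B, task) {
        if (n_B != n_A) { if (n_B > n_A) "B" else "A" }
        else if (task$T > task$t) "B" else "A"
      },
      fill_in = function(options, task) {
        if (task$t < task$T) max(options) else min(options)
      }
    )
  } else {  # extreme_inequality
    list(
      choose = function(n_A, n_B, task) if (task$T > task$t) "B" else "A",
      fill_in = function(options, task) {
        if (task$t < task$T) min(options) else max(options)
      }
    )
  }
}

#' Population configuration
#'
#' Bundles the study conditions for a simulated PTO survey: the sample
#' size, the mixture of behavioural archetypes, the priors on the
#' parametric latent curve, the logistic choice-noise scale, retest
#' behaviour and demographic quota weights.
#'
#' Defaults emulate the study design: `n = 500` respondents; about 14%
#' of the population pinned at answer bounds (extremes plus
#' non-traders); a parametric core centred on `beta = 0.035` with the
#' gamma prior's mean at `0.646`.
#'
#' @param n population size.
#' @param archetype_weights named non-negative weights over the five
#'   archetypes (normalized internally).
#' @param beta_mean,beta_sd normal prior on `beta`.
#' @param gamma_mean,gamma_sdlog lognormal prior on `gamma`, parameterized
#'   by its mean and log-scale sd.
#' @param noise_scale logistic choice-noise scale on log value
#'   differences (0 = deterministic choices).
#' @param retest_jitter scale of the zero-mean perturbation applied to
#'   `(beta, gamma)` before the second round (0 = identical latents).
#' @param retest_fraction share of respondents recontacted for round 2.
#' @param demographic_weights named list of named probability vectors
#'   for the categorical demographics.
#' @param linkage optional named list mapping `variable:level` (e.g.
#'   `income = list(mid = list(gamma_mult = 0.93))`) to multiplicative
#'   shifts of the latent parameters, emulating subgroup effects.
#' @return a list of class `pto_population_config`.
#' @export
pto_population_config <- function(
    n = 500,
    archetype_weights = c(parametric = 0.80, maximizer = 0.06,
                          extreme_egalitarian = 0.015,
                          extreme_inequality = 0.015, non_trader = 0.11),
    beta_mean = 0.035, beta_sd = 0.02,
    gamma_mean = 0.646, gamma_sdlog = 0.35,
    noise_scale = 0.25,
    retest_jitter = 1, retest_fraction = 0.484,
    demographic_weights = NULL,
    linkage = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(names(archetype_weights)) ||
      !all(names(archetype_weights) %in% ARCHETYPES))
    stop("archetype_weights must be named with archetypes: ",
         paste(ARCHETYPES, collapse = ", "))
  if (any(archetype_weights < 0) || sum(archetype_weights) <= 0)
    stop("archetype_weights must be non-negative and sum to a positive value")
  w <- archetype_weights / sum(archetype_weights)
  if (is.null(demographic_weights)) {
    demographic_weights <- list(
      sex = c(female = 0.498, male = 0.502),
      education = c(primary_or_less = 0.248, secondary = 0.502, tertiary = 0.25),
      income = c(low = 0.40, mid = 0.35, high = 0.25),
      residence = c(urban = 0.638, rural = 0.362),
      health = c(good = 0.7, other = 0.3)
    )
  }
  structure(list(
    n = as.integer(n), archetype_weights = w,
    beta_mean = beta_mean, beta_sd = beta_sd,
    gamma_mean = gamma_mean, gamma_sdlog = gamma_sdlog,
    noise_scale = noise_scale,
    retest_jitter = retest_jitter, retest_fraction = retest_fraction,
    demographic_weights = demographic_weights, linkage = linkage),
    class = "pto_population_config")
}

#' Draw a synthetic respondent population
#'
#' Samples demographics (independent quota-style categorical draws plus
#' an age in 18-80), an archetype, and latent curve parameters for each
#' respondent. With a `linkage` entry in the config, the named
#' demographic levels shift the parametric latents multiplicatively,
#' which is how subgroup effects are emulated.
#'
#' @param config a [pto_population_config()].
#' @return data frame with one row per respondent: demographics,
#'   `archetype`, `beta`, `gamma`, `noise_scale`, `nt_side`.
#' @export
sample_population <- function(config) {
  n <- config$n
  draw <- function(w) names(w)[sample.int(length(w), n, replace = TRUE, prob = w)]
  dw <- config$demographic_weights
  age <- round(stats::runif(n, 18, 80))
  prof <- data.frame(
    respondent_id = sprintf("r%04d", seq_len(n)),
    age = age,
    age_band = cut(age, c(17, 40, 59, Inf), labels = c("18-40", "41-59", "60+")),
    stringsAsFactors = FALSE
  )
  for (v in names(dw)) prof[[v]] <- draw(dw[[v]])
  w <- config$archetype_weights
  prof$archetype <- names(w)[sample.int(length(w), n, replace = TRUE, prob = w)]
  prof$beta <- stats::rnorm(n, config$beta_mean, config$beta_sd)
  meanlog <- log(config$gamma_mean) - config$gamma_sdlog^2 / 2
  prof$gamma <- stats::rlnorm(n, meanlog, config$gamma_sdlog)
  prof$noise_scale <- rep(config$noise_scale, n)
  prof$nt_side <- sample(c("people", "gains"), n, replace = TRUE)
  prof$archetype <- factor(prof$archetype, levels = ARCHETYPES)
  # optional demographic -> latent linkage
  for (v in names(config$linkage)) {
    for (lev in names(config$linkage[[v]])) {
      sel <- prof[[v]] == lev
      adj <- config$linkage[[v]][[lev]]
      if (!is.null(adj$gamma_mult)) prof$gamma[sel] <- prof$gamma[sel] * adj$gamma_mult
      if (!is.null(adj$beta_mult)) prof$beta[sel] <- prof$beta[sel] * adj$beta_mult
    }
  }
  prof
}

# Vectorized choice rule for a cohort at one question (fixed task).
# u: latent value of t per respondent; returns logical "chose B".
cohort_choose_B <- function(n_B, task, arch, u, noise) {
  n_B <- rep_len(n_B, length(u))
  d <- log(n_B * task$T) - log(task$P * u)
  pB <- ifelse(noise > 0, stats::plogis(d / noise), as.numeric(d > 0))
  b <- stats::runif(length(u)) < pB
  ega <- arch == "extreme_egalitarian"
  ineq <- arch == "extreme_inequality"
  if (any(ega))
    b[ega] <- if (all(n_B == task$P)) task$T > task$t else (n_B[ega] > task$P)
  if (any(ineq)) b[ineq] <- task$T > task$t
  b
}

#' Elicit one task from a whole cohort (vectorized engine)
#'
#' Runs the same three-step procedure as [run_elicitation()] for every
#' respondent simultaneously, maintaining per-respondent brackets. With
#' `noise_scale = 0` it agrees with the scalar engine answer-for-answer;
#' with noise it is the scalable way to simulate a survey.
#'
#' @param task a one-row task.
#' @param profiles a population data frame from [sample_population()].
#' @return data frame with `respondent_id`, `task_id`, `p` (`NA` when
#'   excluded at the gate), `n_questions`, `excluded_gate`.
#' @export
elicit_cohort <- function(task, profiles) {
  n <- nrow(profiles)
  arch <- as.character(profiles$archetype)
  arch[arch == "non_trader"] <-
    ifelse(profiles$nt_side[arch == "non_trader"] == "people",
           "extreme_egalitarian", "extreme_inequality")
  beta <- ifelse(arch == "maximizer", 0, profiles$beta)
  gamma <- ifelse(arch == "maximizer", 1, profiles$gamma)
  noise <- ifelse(arch %in% c("parametric"), profiles$noise_scale, 0)
  u <- latent_social_value(beta, gamma, task$t)
  nq <- rep(1L, n)

  # step 1: gate at n_B = P, re-ask once
  choseB <- cohort_choose_B(task$P, task, arch, u, noise)
  expectB <- task$t < task$T
  flagged <- choseB != expectB
  if (any(flagged)) {
    nq[flagged] <- nq[flagged] + 1L
    redo <- cohort_choose_B(task$P, task, arch[flagged], u[flagged], noise[flagged])
    flagged[flagged] <- redo != expectB
  }
  excluded <- flagged
  active <- !excluded

  lower <- rep(NA_real_, n); upper <- rep(NA_real_, n)
  if (task$t < task$T) {
    lower[active] <- 0; upper[active] <- task$P
  } else {
    lower[active] <- task$P; upper[active] <- task$answer_upper
    # second question at n_B = 100
    nq[active] <- nq[active] + 1L
    b <- cohort_choose_B(100, task, arch[active], u[active], noise[active])
    idx <- which(active)
    lower[idx[!b]] <- 100              # open-ended 100-200, terminal
    upper[idx[b]] <- 100
    # first follow-up halves 100 -> 50 for those still bisecting
    bi <- idx[b]
    if (length(bi)) {
      nq[bi] <- nq[bi] + 1L
      b2 <- cohort_choose_B(50, task, arch[bi], u[bi], noise[bi])
      upper[bi[b2]] <- 50
      lower[bi[!b2]] <- 50
    }
  }

  repeat {
    open <- active & (upper - lower > WIDTH_STOP) &
      !(task$t > task$T & lower >= 100)
    if (!any(open)) break
    nb <- bisect_mid(lower[open], upper[open])
    nq[open] <- nq[open] + 1L
    b <- cohort_choose_B(nb, task, arch[open], u[open], noise[open])
    idx <- which(open)
    upper[idx[b]] <- nb[b]
    lower[idx[!b]] <- nb[!b]
  }

  # terminal fill-in
  p <- rep(NA_real_, n)
  lo <- pmax(lower, task$answer_lower)
  hi <- pmin(upper, task$answer_upper)
  para <- active & (arch %in% c("parametric", "maximizer"))
  if (any(para)) {
    q <- task$P * u[para] / 10
    p[para] <- pmin(pmax(ceiling(q - 0.5), lo[para]), hi[para])
  }
  small <- task$t < task$T
  ega <- active & arch == "extreme_egalitarian"
  ineq <- active & arch == "extreme_inequality"
  p[ega] <- if (small) hi[ega] else lo[ega]
  p[ineq] <- if (small) lo[ineq] else hi[ineq]

  data.frame(respondent_id = profiles$respondent_id,
             task_id = task$task_id, p = p, n_questions = nq,
             excluded_gate = excluded, stringsAsFactors = FALSE)
}

#' Elicit the full battery from a population
#'
#' Assigns questionnaire versions (random 50/50 split unless a `version`
#' column is already present), then elicits every task from every
#' respondent in the version's presentation order.
#'
#' @param profiles population data frame.
#' @param tasks a task table.
#' @param round round label (1 or 2).
#' @return long response data frame: `respondent_id`, `version`,
#'   `task_id`, `round`, `p`, `n_questions`, `excluded_gate`.
#' @export
elicit_population <- function(profiles, tasks = pto_tasks(), round = 1L) {
  if (is.null(profiles$version))
    profiles$version <- sample(c("ascending", "descending"),
                               nrow(profiles), replace = TRUE)
  out <- list()
  for (v in c("ascending", "descending")) {
    pv <- profiles[profiles$version == v, , drop = FALSE]
    if (!nrow(pv)) next
    seq_tasks <- task_sequence(v, tasks)
    for (i in seq_len(nrow(seq_tasks))) {
      r <- elicit_cohort(seq_tasks[i, , drop = FALSE], pv)
      r$version <- v
      r$round <- round
      out[[length(out) + 1L]] <- r
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$respondent_id, match(res$task_id, tasks$task_id)), ]
  rownames(res) <- NULL
  res[, c("respondent_id", "version", "task_id", "round",
          "p", "n_questions", "excluded_gate")]
}

#' Re-elicit a second round two weeks later
#'
#' Perturbs each recontacted respondent's latent parameters with
#' zero-mean noise scaled by the config's `retest_jitter` (`beta` gets
#' additive normal noise with sd `0.02 * jitter`; `gamma` multiplicative
#' lognormal noise with log-sd `0.25 * jitter`) and re-runs the battery.
#' With `retest_jitter = 0` and `noise_scale = 0` the second round
#' reproduces the first exactly.
#'
#' @param profiles population data frame (with `version` assigned).
#' @param config the population config (for jitter and fraction).
#' @param tasks task table.
#' @param subsample if `TRUE`, recontact only a `retest_fraction` share.
#' @return responses data frame with `round = 2`.
#' @export
second_round <- function(profiles, config, tasks = pto_tasks(),
                         subsample = TRUE) {
  keep <- if (subsample) {
    sort(sample.int(nrow(profiles), round(config$retest_fraction * nrow(profiles))))
  } else seq_len(nrow(profiles))
  pv <- profiles[keep, , drop = FALSE]
  j <- config$retest_jitter
  if (j > 0) {
    pv$beta <- pv$beta + stats::rnorm(nrow(pv), 0, 0.02 * j)
    pv$gamma <- pv$gamma * stats::rlnorm(nrow(pv), 0, 0.25 * j)
  }
  elicit_population(pv, tasks, round = 2L)
}
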