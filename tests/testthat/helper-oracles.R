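# Independent oracles and small fixtures, built in code.

# Brute-force re-derivation of the five-category preference taxonomy,
# written directly from the rule table (kept deliberately separate from
# classify_response's vectorized arithmetic).
oracle_classify <- function(t, T, P, lower, upper, p) {
  pbar <- P * t / T
  if (t < T) {
    if (p == upper) return("extreme_egalitarianism")
    if (p == lower) return("extreme_inequality_seeking")
    if (p == pbar) return("maximizing")
    if (p < pbar) return("concentration")
    return("diffusion")
  } else {
    if (p == upper) return("extreme_inequality_seeking")
    if (p == lower) return("extreme_egalitarianism")
    if (p == pbar) return("maximizing")
    if (p > pbar) return("concentration")
    return("diffusion")
  }
}

# A homogeneous parametric population with chosen latents.
make_profiles <- function(n, beta = 0.035, gamma = 0.646, noise = 0,
                          archetype = "parametric") {
  data.frame(
    respondent_id = sprintf("r%04d", seq_len(n)),
    archetype = archetype, beta = beta, gamma = gamma,
    noise_scale = noise, nt_side = "people",
    stringsAsFactors = FALSE
  )
}

# Exact (granularity-free) responses from latent parameters: p* clipped
# to bounds but not rounded to the option grid.
exact_responses <- function(profiles, tasks = pto_tasks()) {
  do.call(rbind, lapply(seq_len(nrow(tasks)), function(i) {
    task <- tasks[i, ]
    data.frame(respondent_id = profiles$respondent_id,
               version = "ascending",
               task_id = task$task_id, round = 1L,
               p = latent_indifference(profiles$beta, profiles$gamma, task),
               stringsAsFactors = FALSE)
  }))
}

# Table of printed per-program mean indifference counts used in the
# pairwise-direction reproduction (five tasks plus the comparator).
printed_means <- function() {
  rbind(data.frame(t = c(1, 2, 5, 20, 50), P = c(100, 50, 20, 5, 2),
                   mean_p = c(38.0, 17.4, 9.4, 32.2, 37.7)),
        comparator_program())
}
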