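tasks <- pto_tasks()

test_that("the latent curve is normalized at the comparator gain", {
  expect_equal(latent_social_value(0, 1, 7), 7)          # linear limit
  for (b in c(-0.05, 0, 0.08)) for (g in c(0.3, 0.646, 1.4))
    expect_equal(latent_social_value(b, g, 10), 10)
  expect_equal(latent_social_value(0.035, 0.646, 1),
               10 * exp(-0.315) * 10^(-0.646), tolerance = 1e-12)
  expect_equal(latent_social_value(0.035, 0.646, 1), 1.6489, tolerance = 1e-4)
  expect_error(latent_social_value(0, 1, -1), "positive")
})

test_that("latent indifference counts follow p* = P u(t) / 10", {
  t1 <- task_by_id(tasks, "t1")
  expect_equal(latent_indifference(0, 1, tasks), rep(10, 5))   # maximizer
  expect_equal(latent_indifference(0.035, 0.646, t1), 16.489, tolerance = 1e-3)
  # inversion: a curve with u(1) = 3.8 puts indifference at 38 of 100
  g <- 1 - log10(3.8)  # beta = 0: solve 10^(1-gamma) = 3.8 for gamma
  expect_equal(latent_indifference(0, g, t1), 38, tolerance = 1e-9)
  # clipping to the answer range
  expect_equal(latent_indifference(0.2, 3, task_by_id(tasks, "t50")), 200)
})

test_that("archetype policies land on their defining answers", {
  for (i in seq_len(nrow(tasks))) {
    task <- tasks[i, ]
    expect_equal(run_elicitation(task, make_policy("maximizer"))$p, 10,
                 info = task$task_id)
    ega <- run_elicitation(task, make_policy("extreme_egalitarian"))$p
    ineq <- run_elicitation(task, make_policy("extreme_inequality"))$p
    if (task$t < task$T) {
      expect_equal(ega, task$answer_upper)
      expect_equal(ineq, task$answer_lower)
    } else {
      expect_equal(ega, task$answer_lower)
      expect_equal(ineq, task$answer_upper)
    }
    # non-traders mirror one of the extremes
    expect_equal(run_elicitation(task, make_policy("non_trader", side = "people"))$p, ega)
    expect_equal(run_elicitation(task, make_policy("non_trader", side = "gains"))$p, ineq)
  }
})

test_that("zero-noise parametric respondents elicit within option granularity", {
  grid <- expand.grid(beta = seq(-0.1, 0.1, length.out = 6),
                      gamma = seq(0.2, 1.5, length.out = 6))
  for (i in seq_len(nrow(tasks))) {
    task <- tasks[i, ]
    for (j in seq_len(nrow(grid))) {
      pol <- make_policy("parametric", grid$beta[j], grid$gamma[j], 0)
      r <- run_elicitation(task, pol)
      if (r$excluded_gate) next  # curve values 1y above 10y: gate rejects
      q <- latent_indifference(grid$beta[j], grid$gamma[j], task)
      expect_lte(abs(r$p - q), 1)
    }
  }
})

test_that("population sampling is seeded and respects archetype weights", {
  cfg <- pto_population_config(n = 500)
  set.seed(11); a <- sample_population(cfg)
  set.seed(11); b <- sample_population(cfg)
  expect_identical(a, b)
  cfg1 <- pto_population_config(n = 100, archetype_weights = c(parametric = 1))
  set.seed(1)
  expect_true(all(sample_population(cfg1)$archetype == "parametric"))
  expect_error(pto_population_config(archetype_weights = c(wizard = 1)),
               "archetype")
  expect_error(pto_population_config(
    archetype_weights = c(parametric = -1, maximizer = 2)), "non-negative")
})

test_that("elicited category shares converge to archetype weights", {
  # archetypes chosen to map 1:1 onto categories in the t = 1 task
  w <- c(maximizer = 0.2, extreme_egalitarian = 0.1,
         extreme_inequality = 0.1, parametric = 0.6)
  set.seed(21)
  cfg <- pto_population_config(n = 4000, archetype_weights = w,
                               beta_mean = 0, beta_sd = 0,
                               gamma_mean = 0.5, gamma_sdlog = 0,
                               noise_scale = 0)
  prof <- sample_population(cfg)
  r <- elicit_cohort(task_by_id(tasks, "t1"), prof)
  shares <- 100 * table(classify_response(task_by_id(tasks, "t1"), r$p)) / nrow(r)
  # gamma = 0.5, beta = 0 puts the parametric mass at p = 32: diffusion
  expect_equal(unname(shares[["maximizing"]]), 20, tolerance = 0.12)
  expect_equal(unname(shares[["extreme_egalitarianism"]]), 10, tolerance = 0.2)
  expect_equal(unname(shares[["extreme_inequality_seeking"]]), 10, tolerance = 0.2)
  expect_equal(unname(shares[["diffusion"]]), 60, tolerance = 0.1)
})

test_that("the retest round reproduces round 1 when jitter and noise are zero", {
  cfg <- pto_population_config(n = 60, noise_scale = 0, retest_jitter = 0)
  set.seed(5)
  prof <- sample_population(cfg)
  prof$version <- "ascending"
  r1 <- elicit_population(prof, tasks)
  r2 <- second_round(prof, cfg, tasks, subsample = FALSE)
  expect_equal(r2$p, r1$p)
  expect_equal(icc_test_retest(r1, r2, tasks)$mean_icc, 1)
})

test_that("retest agreement degrades as jitter grows", {
  iccs <- vapply(c(0, 1, 4), function(j) {
    cfg <- pto_population_config(n = 150, noise_scale = 0, retest_jitter = j,
                                 archetype_weights = c(parametric = 1))
    set.seed(33)
    prof <- sample_population(cfg)
    prof$version <- "ascending"
    r1 <- elicit_population(prof, tasks)
    r2 <- second_round(prof, cfg, tasks, subsample = FALSE)
    icc_test_retest(r1, r2, tasks)$mean_icc
  }, numeric(1))
  expect_equal(iccs[1], 1)
  expect_true(all(diff(iccs) < 0))
})
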