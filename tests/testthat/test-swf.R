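tasks <- pto_tasks()

test_that("social values rescale indifference counts to the comparator", {
  r <- data.frame(respondent_id = c("a", "a", "a"),
                  task_id = c("t1", "t5", "t50"), p = c(38, 10, 20))
  sv <- social_values(r, tasks)
  expect_equal(sv$u, c(3.8, 5.0, 100))
  expect_error(social_values(data.frame(respondent_id = "a", task_id = "t1",
                                        p = 0), tasks), "positive")
  expect_error(social_values(data.frame(respondent_id = "a", task_id = "zz",
                                        p = 5), tasks), "unknown task_id")
})

test_that("the OLS fit recovers generating parameters exactly without granularity", {
  prof <- make_profiles(50, beta = 0.035, gamma = 0.646)
  fit <- pto_swf(exact_responses(prof, tasks), tasks, exclude_extremes = FALSE)
  expect_equal(unname(coef(fit)[["b_t"]]), 0.035, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["a3"]]), 0.646, tolerance = 1e-6)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-9)
  # maximizer population: u = t exactly, so b = 0, a = 1
  profm <- make_profiles(20, beta = 0, gamma = 1)
  fitm <- pto_swf(exact_responses(profm, tasks), tasks, exclude_extremes = FALSE)
  expect_equal(unname(coef(fitm)[["b_t"]]), 0, tolerance = 1e-9)
  expect_equal(unname(coef(fitm)[["a3"]]), 1, tolerance = 1e-9)
  # refitting on fitted values is idempotent
  refit_data <- fit$data
  refit_data$u <- exp(fitted(fit))
  refit <- pto_swf(
    data.frame(respondent_id = refit_data$respondent_id,
               task_id = refit_data$task_id,
               p = refit_data$u * tasks$P[match(refit_data$task_id, tasks$task_id)] / 10),
    tasks, exclude_extremes = FALSE)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-9)
})

test_that("full elicitation granularity costs at most a few percent", {
  set.seed(3)
  cfg <- pto_population_config(n = 500, archetype_weights = c(parametric = 1),
                               beta_sd = 0, gamma_sdlog = 0, noise_scale = 0)
  prof <- sample_population(cfg)
  prof$version <- "ascending"
  resp <- elicit_population(prof, tasks)
  fit <- pto_swf(resp, tasks)
  expect_equal(unname(coef(fit)[["b_t"]]), 0.035, tolerance = 0.05)
  expect_equal(unname(coef(fit)[["a3"]]), 0.646, tolerance = 0.05)
})

test_that("rescaling all social values shifts only the intercept", {
  prof <- make_profiles(30, beta = 0.02, gamma = 0.8)
  r <- exact_responses(prof, tasks)
  f1 <- pto_swf(r, tasks, exclude_extremes = FALSE)
  r2 <- r; r2$p <- r2$p * 3  # u scales by 3
  f2 <- pto_swf(r2, tasks, exclude_extremes = FALSE)
  expect_equal(coef(f2)[["b_t"]], coef(f1)[["b_t"]], tolerance = 1e-9)
  expect_equal(coef(f2)[["a3"]], coef(f1)[["a3"]], tolerance = 1e-9)
  expect_equal(coef(f2)[["ln_alpha1"]] - coef(f1)[["ln_alpha1"]], log(3),
               tolerance = 1e-9)
  expect_equal(f2$threshold, f1$threshold, tolerance = 1e-9)
})

test_that("closed-form and numeric thresholds agree", {
  cases <- expand.grid(b = c(0.01, 0.035, 0.08), a = c(0.3, 0.646, 0.9))
  for (i in seq_len(nrow(cases))) {
    cf <- swf_threshold(cases$b[i], cases$a[i])
    nm <- swf_threshold_numeric(cases$b[i], cases$a[i])
    expect_equal(cf$threshold, nm$threshold, tolerance = 1e-6)
    expect_equal(cf$direction, nm$direction)
  }
  # power-function limit: no sign change anywhere
  expect_true(is.na(swf_threshold(0, 0.7)$threshold))
  expect_true(is.na(swf_threshold_numeric(0, 0.7)$threshold))
  # mirror case: negative trend with a > 1 flips concavity the other way
  cf <- swf_threshold(-0.035, 1.4)
  nm <- swf_threshold_numeric(-0.035, 1.4)
  expect_equal(cf$roots$root, nm$roots$root, tolerance = 1e-6)
  expect_equal(cf$direction, "pos_to_neg")
})

test_that("prediction reproduces the closed-form curve", {
  fit <- structure(list(coefficients = c(ln_alpha1 = 0.735, b_t = 0.035,
                                         a3 = 0.646)), class = "pto_swf")
  expect_equal(predict(fit, 1), exp(0.735) * exp(0.035), tolerance = 1e-9)
  expect_equal(predict(fit, 1), 2.1598, tolerance = 1e-4)
  expect_equal(predict(fit, 10), 13.098, tolerance = 1e-4)
  lin <- structure(list(coefficients = c(ln_alpha1 = 0, b_t = 0, a3 = 1)),
                   class = "pto_swf")
  expect_equal(predict(lin, c(1, 7, 23)), c(1, 7, 23))
  # second derivative changes sign exactly at the threshold
  thr <- swf_threshold(0.035, 0.646)$threshold
  expect_lt(predict(fit, thr - 0.01, deriv = 2), 0)
  expect_gt(predict(fit, thr + 0.01, deriv = 2), 0)
  expect_error(predict(fit, 0), "positive")
})

test_that("the bootstrap resamples whole respondents and is seeded", {
  set.seed(14)
  prof <- make_profiles(40, beta = 0.035, gamma = 0.646)
  prof$beta <- prof$beta + rnorm(40, 0, 0.01)
  sv <- social_values(exact_responses(prof, tasks), tasks)
  b1 <- bootstrap_threshold(sv, B = 50, seed = 99)
  b2 <- bootstrap_threshold(sv, B = 50, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_equal(length(b1$draws), 50)
  # a homogeneous population has (numerically) zero CI width
  profh <- make_profiles(40, beta = 0.035, gamma = 0.646)
  svh <- social_values(exact_responses(profh, tasks), tasks)
  bh <- bootstrap_threshold(svh, B = 50, seed = 1)
  expect_equal(unname(diff(bh$ci)), 0, tolerance = 1e-9)
  expect_equal(unname(bh$ci[1]), swf_threshold(0.035, 0.646)$threshold,
               tolerance = 1e-6)
  expect_equal(bh$frac_degenerate, 0)
  expect_error(bootstrap_threshold(svh[svh$respondent_id %in%
    unique(svh$respondent_id)[1:5], ], B = 50), ">= 10")
})

test_that("fit objects print, summarise and plot without error", {
  prof <- make_profiles(30, beta = 0.035, gamma = 0.646)
  prof$gamma <- prof$gamma * exp(rnorm(30, 0, 0.1))
  fit <- pto_swf(exact_responses(prof, tasks), tasks,
                 exclude_extremes = FALSE, bootstrap = 30, seed = 2)
  expect_output(print(fit), "threshold")
  expect_output(print(summary(fit)), "Adjusted R-squared")
  expect_length(residuals(fit), fit$n_obs)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("fitting demands enough distinct gain sizes", {
  r <- data.frame(respondent_id = rep("a", 2), task_id = c("t1", "t2"),
                  p = c(30, 20))
  expect_error(pto_swf(r, tasks, exclude_extremes = FALSE), "3 distinct")
})
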