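tasks <- pto_tasks()

test_that("the maximizing-value test behaves and has power at study sizes", {
  h <- test_h1(rep(10, 30))
  expect_equal(h$mean, 10)
  expect_false(h$reject)
  set.seed(8)
  # at the observed effect size (mean 38, sd 20, n = 432) power is ~1
  rejections <- vapply(1:50, function(i)
    test_h1(rnorm(432, 38, 20))$reject, logical(1))
  expect_true(all(rejections))
  # the statistic moves monotonically with a location shift
  x <- rnorm(100, 10, 5)
  stats <- vapply(c(0, 2, 4), function(c) test_h1(x + c)$statistic, numeric(1))
  expect_true(all(diff(stats) > 0))
  expect_error(test_h1(c(10)), "at least 2")
})

test_that("pair directions follow the fewer-beneficiaries rule", {
  p1 <- list(t = 1, P = 100, mean_p = 38.0)
  p2 <- list(t = 2, P = 50, mean_p = 17.4)
  expect_equal(pair_direction(p1, p2)$direction, "D")
  p15a <- list(t = 20, P = 5, mean_p = 32.2)
  p15b <- list(t = 50, P = 2, mean_p = 37.7)
  expect_equal(pair_direction(p15a, p15b)$direction, "C")
  expect_equal(pair_direction(p1, list(t = 9, P = 50, mean_p = 38))$direction,
               "none")
  # order of the arguments does not matter: reordered internally by P
  expect_equal(pair_direction(p2, p1)[, c("t1", "t2", "direction")],
               pair_direction(p1, p2)[, c("t1", "t2", "direction")])
  expect_error(pair_direction(p1, list(t = 3, P = 100, mean_p = 5)),
               "differ in beneficiary count")
})

test_that("all_pairs enumerates C(n,2) ordered comparisons", {
  m <- printed_means()
  ap <- all_pairs(m)
  expect_equal(nrow(ap), 15)
  expect_true(all(ap$P1 > ap$P2))
  ap5 <- all_pairs(m[m$t != 10, ])
  expect_equal(nrow(ap5), 10)
  # attaching data yields finite test statistics
  set.seed(4)
  d <- list("1" = rnorm(50, 38, 10), "2" = rnorm(50, 17, 5),
            "5" = rnorm(50, 9, 3), "20" = rnorm(50, 32, 10),
            "50" = rnorm(50, 38, 12))
  apd <- all_pairs(m, data = d)
  expect_true(all(is.finite(apd$p_value)))
})

test_that("version consistency detects an injected order effect", {
  set.seed(6)
  mkresp <- function(shift) {
    n <- 240
    do.call(rbind, lapply(tasks$task_id, function(id) data.frame(
      respondent_id = sprintf("r%03d", 1:n),
      version = rep(c("ascending", "descending"), each = n / 2),
      task_id = id,
      p = c(rnorm(n / 2, 20, 5), rnorm(n / 2, 20 + shift, 5)))))
  }
  null_vc <- version_consistency(mkresp(0), tasks)
  expect_equal(nrow(null_vc), 5)
  eff_vc <- version_consistency(mkresp(10), tasks)
  expect_true(all(eff_vc$p_value < 0.001))
  expect_gt(mean(null_vc$p_value), mean(eff_vc$p_value))
  one <- mkresp(0); one <- one[one$version == "ascending", ]
  expect_error(version_consistency(one, tasks), "both questionnaire versions")
})

test_that("ICC(A,1) matches the two-way ANOVA mean squares from aov", {
  set.seed(12)
  x1 <- rnorm(40, 20, 6); x2 <- x1 + rnorm(40, 0, 2)
  # independent route: mean squares from base aov on the long layout
  long <- data.frame(y = c(x1, x2),
                     subj = factor(rep(1:40, 2)),
                     rater = factor(rep(1:2, each = 40)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  want <- (msr - mse) / (msr + mse + 2 / 40 * (msc - mse))
  expect_equal(icc_agreement(x1, x2), want, tolerance = 1e-10)
  expect_equal(icc_agreement(x1, x1), 1)
  # independent measurements agree at chance level
  set.seed(13)
  iccs <- vapply(1:200, function(i)
    icc_agreement(rnorm(30), rnorm(30)), numeric(1))
  expect_lt(abs(mean(iccs)), 0.08)
  expect_error(icc_agreement(1, 2), "at least 2")
})

test_that("subgroup analysis applies Bonferroni and skips tiny groups", {
  set.seed(17)
  cfg <- pto_population_config(n = 200, noise_scale = 0.25)
  prof <- sample_population(cfg)
  prof$version <- "ascending"
  resp <- elicit_population(prof, tasks)
  sg <- subgroup_analysis(resp, prof, "residence", tasks)
  m <- sg$m_comparisons
  expect_equal(m, 2 * 5)
  expect_equal(sg$comparisons$p_bonferroni,
               pmin(1, sg$comparisons$p_value * m))
  # adjustment never increases the rejection count
  expect_lte(sum(sg$comparisons$p_bonferroni < 0.05, na.rm = TRUE),
             sum(sg$comparisons$p_value < 0.05, na.rm = TRUE))
  # subgroups drawn from the same population: nothing significant
  expect_false(any(sg$comparisons$significant))
  # a tiny subgroup gets no threshold, with a notice
  prof$tiny <- ifelse(seq_len(nrow(prof)) <= 5, "yes", "no")
  sg2 <- subgroup_analysis(resp, prof, "tiny", tasks)
  expect_true(is.na(sg2$thresholds$threshold[sg2$thresholds$group == "yes"]))
  expect_match(sg2$thresholds$note[sg2$thresholds$group == "yes"], "skipped")
  expect_error(subgroup_analysis(resp, prof, "shoe_size", tasks), "not found")
})

test_that("a latent-shifted subgroup shows a higher threshold", {
  # lower gamma lifts the flip point: emulate an income-linked preference
  set.seed(18)
  cfg <- pto_population_config(
    n = 400, archetype_weights = c(parametric = 1), noise_scale = 0,
    linkage = list(income = list(mid = list(gamma_mult = 0.90))))
  prof <- sample_population(cfg)
  prof$version <- "ascending"
  resp <- elicit_population(prof, tasks)
  sg <- subgroup_analysis(resp, prof, "income", tasks)
  thr <- sg$thresholds
  pop_fit <- pto_swf(resp, tasks)
  expect_gt(thr$threshold[thr$group == "mid"], pop_fit$threshold)
})
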