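# ptoswf

Person trade-off (PTO) elicitation and health-related social welfare
function (SWF) estimation in R.

## The problem

Cost-effectiveness analysis values each additional QALY equally, no
matter whether a fixed budget of health gains is spread thinly over
many patients or concentrated on a few. The PTO technique tests that
assumption empirically: respondents compare program A (`P` patients
each gaining `t` years in full health) with program B (`p` patients
each gaining `T = 10` years) and state the `p` at which the programs
are equally good. Across the five-task battery the gain `t` takes the
values 1, 2, 5, 20 and 50 years while total gains are fixed at
`P * t = 100` person-years, so a pure maximizer answers
`p = P*t/T = 10` everywhere and any deviation reveals a distributive
preference — *diffusion* (spread small gains widely) or
*concentration* (focus large gains on a few).

The package is aimed at health-economics researchers who want to
design, simulate, and analyse such studies end-to-end:

* the task battery and questionnaire orders (`pto_tasks()`,
  `task_sequence()`);
* the three-step adaptive elicitation engine — rationality gate,
  bisection ladder, bounded open-ended finish (`run_elicitation()`,
  `elicit_cohort()`);
* a seeded synthetic population with latent SWF parameters, behavioural
  archetypes and choice noise (`pto_population_config()`,
  `sample_population()`);
* classification into the five preference types and non-trade-off
  exclusion (`classify_response()`, `flag_nontradeoff()`);
* hypothesis tests, order-consistency checks, test–retest ICC and
  Bonferroni-corrected subgroup analysis (`test_h1()`, `all_pairs()`,
  `icc_test_retest()`, `subgroup_analysis()`);
* the model core: an OLS fit of the SWF
  `u(t) = a1 * exp(b*t) * t^a` on social values `u = 10*p/P`, the
  health-gain threshold `t* = (sqrt(a) - a)/b` where `u''` changes
  sign, and a respondent-level percentile bootstrap for its CI
  (`pto_swf()`, `swf_threshold()`).

## Worked example

Simulate a full study under the default conditions (500 respondents,
logistic choice noise, 1000 bootstrap replications) and print the
report:

```r
library(ptoswf)
study <- run_pto_study(pto_config(bootstrap = 1000, seed = 42))
print(study)
#> Simulated PTO study: 500 respondents, 90 excluded as non-trade-off
#>
#> Preference type distribution (% per task):
#>                              t1   t2   t5  t20  t50
#> concentration               9.6 13.8 12.3 56.3 62.1
#> diffusion                  62.2 55.2 29.2 17.6 13.8
#> maximizing                 13.0 16.0 43.3 10.9  8.4
#> extreme_egalitarianism      7.0  7.0  7.1  7.1  7.0
#> extreme_inequality_seeking  8.2  8.0  8.1  8.1  8.6
#>
#> Mean indifference counts (trade-off respondents):
#>   t   P   n mean_p   sd_p p_vs_10
#>   1 100 410 19.132 11.515       0
#>   2  50 410 14.480  6.444       0
#>   5  20 410 10.773  2.180       0
#>  20   5 410 13.137  6.754       0
#>  50   2 410 33.888 33.062       0
#>
#> Social welfare function fit: u(t) = a1 * exp(b*t) * t^a
#>   observations: 2050 (410 respondents)
#>   a1 = 1.533   b = 0.032   a = 0.696   adj R2 = 0.889
#>   threshold: 4.320 years (neg_to_pos)
#>   95% percentile bootstrap CI: [3.947, 4.690] (B = 1000, 0.0% degenerate)
#>
#> Test-retest ICC per task:
#>    t1    t2    t5   t20   t50
#> 0.913 0.870 0.845 0.982 0.775
```

Reading the output: diffusion dominates the small-gain tasks and
concentration the large-gain ones; the one-sample tests against 10
(`p_vs_10`) reject QALY-neutrality in every task; the fitted SWF flips
from convex-decreasing to concave-increasing marginal value at about
4.3 years (the generating population was centred on a flip point of
4.51 years — the small shortfall is the cost of integer answer
granularity), with a bootstrap CI of roughly 3.9–4.7 years. Below the
threshold respondents prefer spreading gains; above it, concentrating
them. `plot(study$fit)` draws the fitted `u(t)` and `u''(t)` curves,
and `write_report(study, "out/")` saves all tables as CSV plus a JSON
summary.

`vignettes/pto-methods.Rmd` documents the model, the elicitation
reconstruction, the generator's assumptions and the numerical choices.

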