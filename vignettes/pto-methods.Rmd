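---
title: "Person trade-off elicitation and the health-gain threshold: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person trade-off elicitation and the health-gain threshold: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptoswf)
```

## The scientific question

When a fixed budget of health gains can be spread thinly over many
patients or concentrated on a few, which allocation does the public
prefer? The person trade-off (PTO) technique answers this by asking
respondents to act as social decision makers: program A gives each of
`P` patients `t` extra years in full health, program B gives each of
`p` patients `T = 10` years, and the respondent reports the `p` that
makes the programs equally good. Since total gains are held fixed at
`P * t = 100` person-years across the battery (`t` = 1, 2, 5, 20, 50),
deviations of `p` from the maximizing value `P*t/T = 10` reveal
distributive preferences: `p > 10` for a small-gain program means small
gains to many are valued above their person-year content (diffusion);
the reverse pattern reveals a taste for concentration.

The package's model core is the health-related social welfare function

$$u(t) = \alpha_1 e^{b t} t^{a},$$

log-linearized to `ln u = ln(alpha1) + b*t + a*ln(t)` and fitted by OLS
to individual-level social values `u = 10*p/P` (the comparator scale is
fixed by defining `u(10) = 10`). Its second derivative
`u''(t) = u(t) * ((b + a/t)^2 - a/t^2)` changes sign where
`(b*t + a)^2 = a`; with `b > 0` and `0 < a < 1` the positive root

$$t^* = \frac{\sqrt{a} - a}{b}$$

is the gain size at which preferences flip from diffusion (`u'' < 0`)
to concentration (`u'' > 0`). `swf_threshold()` implements the closed
form; `swf_threshold_numeric()` is an independent sign-scan route used
to cross-check it. With the published coefficient values `b = 0.035`
and `a = 0.646` the root sits at `r round(swf_threshold(0.035, 0.646)$threshold, 3)`
years; coefficients printed to three decimals move such a root by a
couple of percent, which is why threshold comparisons against rounded
published values should carry a ~2% allowance.

## The elicitation engine

Direct statement of `p` is cognitively hard, so the engine approaches
indifference in three steps.

1. **Rationality gate.** The opening choice shows equal beneficiary
   numbers (`P` vs `P`); only the per-person gains differ, so the
   program with larger gains dominates. An unexpected answer pauses the
   interview and re-asks once; a second unexpected answer excludes the
   record. This mirrors a comprehension screen, not a preference.
2. **Bisection ladder.** For `t < 10` the first follow-up halves
   program B's count from `P`; afterwards each question probes the
   bracket midpoint (nearest integer, ties up), with the bracket
   `[lower, upper]` narrowing monotonically until `upper - lower <= 5`.
   For `t > 10` the second question jumps to 100 beneficiaries; if B is
   preferred there, the ladder halves to 50 and then bisects within
   `[P, 100]`; if A is still preferred at 100, the answer is collected
   open-ended on 100-200.
3. **Bounded open-ended finish.** A drop-down offers every integer in
   the terminal bracket, clipped to the task's answer bounds.

Two numerical choices deserve comment.

* **Inclusive terminal options.** Because every choice is forced, an
  answer at count `x` expresses only *weak* preference: a respondent
  indifferent exactly at `x` must still pick a side. Both bracket
  endpoints therefore remain consistent with the recorded choices and
  both are offered in the drop-down. The alternative (excluding probed
  endpoints) looks natural but makes the maximizing answer `p = 10`
  unreachable in the `t = 5` task, where the halving step necessarily
  probes 10 (= 20/2) — contradicting the taxonomy in which maximizers
  answer 10 in every task. Inclusiveness also makes the engine exact:
  for every task and every integer latent indifference point `q` in the
  admissible range, a deterministic respondent with threshold `q` is
  returned `p = q` (the test suite sweeps all ~565 cases).
* **Answer bounds.** The lower bound is 1 beneficiary for the
  small-gain tasks (zero would make `u = 10*p/P` degenerate and `ln u`
  undefined) and `P` for the large-gain tasks, since after a rational
  gate answer the bracket can never fall below the equal-numbers
  starting point; the upper bound is `P` for small gains and 200 for
  large gains. The extreme preference categories are defined at exactly
  these reachable bounds.

A stored trace can be replayed bit-exactly (`replay_trace()`), and the
vectorized cohort engine (`elicit_cohort()`) is tested to agree with
the scalar engine answer-for-answer at zero noise.

## The synthetic population

`sample_population()` draws respondents with a latent curve
`u_i(t) = 10 * exp(beta*(t-10)) * (t/10)^gamma` (so `u_i(10) = 10` by
construction), an archetype, and quota-style demographics. The default
study conditions, chosen once to emulate the design being modelled:

* `n = 500` respondents, randomly split 50/50 over the two
  questionnaire orders (ascending/descending in `t`), with a 48.4%
  retest subsample;
* archetype mixture: 80% parametric, 6% pure maximizers, 1.5% + 1.5%
  extreme egalitarians/inequality-seekers, 11% non-traders. Extremes
  plus non-traders total ~14%, matching the order of magnitude of
  bound-pinned respondents a survey of this kind excludes (about one in
  seven);
* parametric core: `beta ~ N(0.035, 0.02)` and `gamma` lognormal with
  mean 0.646 (`sdlog = 0.35`), centring the population's flip point
  near 4.5 years while allowing realistic heterogeneity, including a
  minority with reversed signs;
* choice noise: logistic on the *log* of total program values with
  scale 0.25. Acting on logs keeps choices invariant to the arbitrary
  scaling of the utility function; 0.25 makes choices near indifference
  noticeably stochastic while leaving clear-cut choices near
  deterministic.
* retest: round 2 re-runs the battery after perturbing `(beta, gamma)`
  with zero-mean noise (`sd = 0.02*jitter` additive on `beta`,
  `sdlog = 0.25*jitter` multiplicative on `gamma`). Jittering latents
  rather than re-drawing archetypes encodes the finding that preference
  *types* are largely stable between rounds.

Non-traders behave lexicographically like one of the two extremes
(side drawn at random): the design cannot distinguish a genuine extreme
preference from a refusal to trade, so the generator does not try to
either; both are flagged by `flag_nontradeoff()` and excluded from mean
tables and the SWF fit, mirroring the analysis plan.

What the generator does **not** emulate: anchoring on drop-down
positions (real respondents favour the larger values in a box),
fatigue and order effects within a session, correlation between
demographics and latents (off by default; an explicit `linkage` map can
induce it), and any calibration to a real panel. Passing tests
therefore demonstrate the correctness and statistical behaviour of the
*pipeline* under a plausible respondent model, not behavioural realism.

## Inference choices

* **Exclusion order.** Respondents with any bound answer are excluded
  once, and the same excluded set feeds the mean tables, the pairwise
  comparisons and the SWF fit.
* **Estimation.** OLS on pooled individual-level observations; with
  respondent heterogeneity the pooled fit estimates the population
  mean coefficients. Adjusted R-squared is reported.
* **Threshold.** Reported as the exact root of the closed form, with
  the numeric scan as a guard (agreement to 1e-6 is asserted); the
  default search interval is (0, 60] years, covering the largest
  elicited gain. `b = 0` (pure power function) yields no sign change
  and an absent threshold; mirrored curves (`b < 0`, `a > 1`) are
  detected and labelled `pos_to_neg`.
* **Bootstrap.** Respondents, not observations, are the independent
  sampling unit, so the percentile bootstrap resamples whole
  respondents (all five observations move together); 1000 replications
  by default. Replicates without a sign change are dropped, their
  fraction is reported, and the interval is flagged unreliable if they
  exceed half.
* **Tests.** All mean comparisons are equal-variance Student's t-tests
  (one-sample against 10 for the maximizing hypothesis; two-sample for
  pairs, versions and subgroups), matching the analysis plan; a paired
  variant is available for within-respondent pairs. Zero-variance data
  (e.g. an all-maximizer simulation, or the degenerate `t = 10`
  comparator) get the limiting test rather than an error. Test-retest
  reliability uses ICC(A,1) — two-way, absolute agreement, single
  measure — the standard form for repeated administrations of the same
  instrument; the Bonferroni family for subgroup analysis is all
  subgroups x tasks within one grouping variable, the most conservative
  natural reading.

## Problem sizes used in the checks

The test suite favours exhaustive small cases over sampled large ones:
the classifier is checked against a brute-force rule table on every
admissible integer answer (~565 cases), and the engine on every integer
indifference point in every task. Statistical behaviour is checked at
the study's own scale (n = 432-500): parameter recovery through the
full elicit-and-fit path at zero noise (within 5%, the cost of integer
granularity; to 1e-6 when granularity is bypassed), threshold CI
coverage with 100 outer repetitions of a 200-replicate bootstrap, and
a 2000-permutation null calibration of the order-consistency test.

## Limitations

Simulated respondents answer a model, not a questionnaire; the
granularity of the terminal drop-down biases fitted coefficients
slightly toward coarser values (visible as a ~2% downward shift of the
recovered threshold at default noise); and the battery's largest gains
(20 and 50 years) leave the upper arm of `u(t)` weakly identified, so
thresholds far above 5 years would extrapolate poorly. The package
exposes every stage as a plain function — the CLI wrapper in
`inst/scripts/run_study.R` only composes them, which is why no separate
command-line tool is shipped.
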