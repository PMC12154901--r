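# Health-related social welfare function u(t) = a1 * exp(b*t) * t^a,
# log-linearized to  ln u = ln(a1) + b*t + a*ln(t)  and fitted by OLS on
# individual-level observations u = 10 * p / P (comparator scale,
# u(10) := 10). The second derivative
#   u''(t) = u(t) * ((b + a/t)^2 - a/t^2)
# changes sign where (b*t + a)^2 = a; the positive root
#   t* = (sqrt(a) - a) / b
# marks the flip between diffusion (u'' < 0, marginally decreasing
# social value) and concentration (u'' > 0).

#' Social-value observations from responses
#'
#' Maps each respondent x task indifference count to the social value
#' of the task's gain on the comparator scale, `u = 10 * p / P`.
#'
#' @param responses long response data frame; callers are expected to
#'   have excluded non-trade-off respondents already (see
#'   [flag_nontradeoff()]).
#' @param tasks task table.
#' @return data frame `respondent_id`, `task_id`, `t`, `u`.
#' @examples
#' r <- data.frame(respondent_id = "r1", task_id = "t1", p = 38)
#' social_values(r)$u   # 3.8
#' @export
social_values <- function(responses, tasks = pto_tasks()) {
  i <- match(responses$task_id, tasks$task_id)
  if (anyNA(i)) stop("unknown task_id in responses")
  if (any(is.na(responses$p) | responses$p <= 0))
    stop("all p must be positive for social values")
  data.frame(respondent_id = responses$respondent_id,
             task_id = responses$task_id,
             t = tasks$t[i],
             u = 10 * responses$p / tasks$P[i],
             stringsAsFactors = FALSE)
}

#' Fit the social welfare function to PTO responses
#'
#' The main fitting function. Excludes non-trade-off respondents (any
#' task answered at a bound), maps the remaining responses to social
#' values, fits `ln u = ln(a1) + b*t + a*ln(t)` by ordinary least
#' squares, locates the health-gain threshold where `u''` changes sign,
#' and (optionally) bootstraps the threshold's percentile confidence
#' interval by resampling respondents (all of a respondent's
#' observations move together).
#'
#' @param responses long response data frame (round 1).
#' @param tasks task table.
#' @param exclude_extremes drop respondents flagged by
#'   [flag_nontradeoff()] before fitting (the default mirrors the
#'   analysis plan; set `FALSE` only if `responses` are pre-filtered).
#' @param bootstrap number of bootstrap replications (0 = none).
#' @param level confidence level for the percentile interval.
#' @param t_max upper end of the threshold search interval, years.
#' @param seed optional seed for the bootstrap resampling.
#' @return an object of class `pto_swf` with components `coefficients`
#'   (`ln_alpha1`, `b_t`, `a3`), `r2_adj`, `n_obs`, `n_respondents`,
#'   `threshold`, `threshold_direction`, `ci`, `boot` and the underlying
#'   `lm` fit. Supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals` and `fitted`.
#' @examples
#' tasks <- pto_tasks()
#' p_star <- round(latent_indifference(0.02, 0.7, tasks))
#' r <- data.frame(respondent_id = "r1", task_id = tasks$task_id, p = p_star)
#' fit <- pto_swf(r, exclude_extremes = FALSE)
#' coef(fit)
#' @export
pto_swf <- function(responses, tasks = pto_tasks(), exclude_extremes = TRUE,
                    bootstrap = 0, level = 0.95, t_max = 60, seed = NULL) {
  cl <- match.call()
  if (exclude_extremes) {
    flags <- flag_nontradeoff(responses, tasks)
    keep <- names(flags)[!flags]
    responses <- responses[responses$respondent_id %in% keep, , drop = FALSE]
  }
  if (!nrow(responses)) stop("no responses left to fit")
  sv <- social_values(responses, tasks)
  if (length(unique(sv$t)) < 3)
    stop("need at least 3 distinct gain sizes t to fit the SWF")
  fit <- stats::lm(log(u) ~ t + log(t), data = sv)
  co <- stats::coef(fit)
  coefs <- c(ln_alpha1 = unname(co[["(Intercept)"]]),
             b_t = unname(co[["t"]]), a3 = unname(co[["log(t)"]]))
  thr <- swf_threshold(coefs[["b_t"]], coefs[["a3"]], t_max = t_max)
  out <- list(
    coefficients = coefs,
    r2_adj = summary(fit)$adj.r.squared,
    n_obs = nrow(sv),
    n_respondents = length(unique(sv$respondent_id)),
    threshold = thr$threshold,
    threshold_direction = thr$direction,
    lm = fit, data = sv, t_max = t_max, level = level,
    ci = NULL, boot = NULL, call = cl)
  class(out) <- "pto_swf"
  if (bootstrap > 0) {
    bt <- bootstrap_threshold(sv, B = bootstrap, level = level,
                              t_max = t_max, seed = seed)
    out$ci <- bt$ci
    out$boot <- bt
  }
  out
}

#' Health-gain threshold of a fitted SWF (closed form)
#'
#' Finds where `u''(t)` changes sign on `(0, t_max]`. The sign of `u''`
#' is the sign of `g(t) = (b*t + a)^2 - a`, so candidate roots are
#' `t = (sqrt(a) - a) / b` and `t = (-sqrt(a) - a) / b`. The reported
#' threshold is the first sign change in the interval, labelled
#' `"neg_to_pos"` (diffusion flips to concentration) or `"pos_to_neg"`.
#' Returns an absent (`NA`) threshold when `u''` never changes sign,
#' e.g. the pure power-function case `b = 0`, `0 < a < 1`.
#'
#' @param b_t coefficient on `t`.
#' @param a3 coefficient on `ln t` (> 0 for a root to exist).
#' @param t_max search interval upper end, years.
#' @return list with `threshold` (years or `NA`), `direction`, and
#'   `roots` (all sign changes in the interval, with directions).
#' @examples
#' swf_threshold(0.035, 0.646)$threshold   # about 4.51 years
#' @export
swf_threshold <- function(b_t, a3, t_max = 60) {
  if (t_max <= 0) stop("t_max must be positive")
  none <- list(threshold = NA_real_, direction = NA_character_,
               roots = data.frame(root = numeric(), direction = character()))
  if (a3 <= 0 || b_t == 0) return(none)
  cand <- sort(c((sqrt(a3) - a3) / b_t, (-sqrt(a3) - a3) / b_t))
  cand <- cand[cand > 0 & cand <= t_max]
  if (!length(cand)) return(none)
  g <- function(t) (b_t * t + a3)^2 - a3
  dirs <- vapply(cand, function(r) {
    eps <- min(r / 2, 1e-4 * max(1, r))
    if (g(r - eps) < 0 && g(r + eps) > 0) "neg_to_pos"
    else if (g(r - eps) > 0 && g(r + eps) < 0) "pos_to_neg"
    else NA_character_
  }, character(1))
  keep <- !is.na(dirs)
  if (!any(keep)) return(none)
  roots <- data.frame(root = cand[keep], direction = dirs[keep],
                      stringsAsFactors = FALSE)
  list(threshold = roots$root[1], direction = roots$direction[1], roots = roots)
}

#' Health-gain threshold by numeric sign scan
#'
#' Independent numeric route: scans the sign of `u''(t)` on a fine grid
#' over `(0, t_max]` and refines each sign change with
#' [stats::uniroot()]. Agrees with [swf_threshold()] to high precision
#' wherever both exist.
#'
#' @inheritParams swf_threshold
#' @param n_grid grid resolution.
#' @return same shape as [swf_threshold()].
#' @export
swf_threshold_numeric <- function(b_t, a3, t_max = 60, n_grid = 20000) {
  if (t_max <= 0) stop("t_max must be positive")
  g <- function(t) (b_t * t + a3)^2 - a3
  ts <- seq(t_max / n_grid, t_max, length.out = n_grid)
  s <- sign(g(ts))
  ch <- which(s[-1] * s[-length(s)] < 0)
  if (!length(ch))
    return(list(threshold = NA_real_, direction = NA_character_,
                roots = data.frame(root = numeric(), direction = character())))
  roots <- vapply(ch, function(i)
    stats::uniroot(g, c(ts[i], ts[i + 1]), tol = 1e-12)$root, numeric(1))
  dirs <- ifelse(s[ch] < 0, "neg_to_pos", "pos_to_neg")
  rdf <- data.frame(root = roots, direction = dirs, stringsAsFactors = FALSE)
  list(threshold = rdf$root[1], direction = rdf$direction[1], roots = rdf)
}

#' Percentile bootstrap for the SWF threshold
#'
#' Resamples respondents with replacement (cluster bootstrap: a
#' respondent's five observations always move together), refits the
#' log-linear SWF and recomputes the threshold per replicate, and takes
#' percentile quantiles over the replicates with a defined threshold.
#' Replicates whose `u''` never changes sign are dropped and their
#' fraction reported; the interval is flagged unreliable when fewer
#' than half the replicates yield a threshold.
#'
#' @param sv social-value observations from [social_values()].
#' @param B number of replications (>= 100 recommended).
#' @param level confidence level.
#' @param t_max threshold search interval upper end.
#' @param seed optional seed.
#' @return list with `ci` (named length-2 vector), `draws`,
#'   `frac_degenerate`, `reliable`, `B`.
#' @export
bootstrap_threshold <- function(sv, B = 1000, level = 0.95, t_max = 60,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(sv$respondent_id)
  if (length(ids) < 10) stop("bootstrap needs responses from >= 10 respondents")
  idx <- split(seq_len(nrow(sv)), factor(sv$respondent_id, levels = ids))
  X <- cbind(1, sv$t, log(sv$t))
  y <- log(sv$u)
  draws <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- unlist(idx[sample.int(length(ids), replace = TRUE)],
                   use.names = FALSE)
    co <- stats::lm.fit(X[take, , drop = FALSE], y[take])$coefficients
    draws[b] <- swf_threshold(co[2], co[3], t_max = t_max)$threshold
  }
  ok <- draws[!is.na(draws)]
  alpha <- (1 - level) / 2
  ci <- if (length(ok)) stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
        else c(NA_real_, NA_real_)
  names(ci) <- paste0(100 * c(alpha, 1 - alpha), "%")
  list(ci = ci, draws = draws, frac_degenerate = mean(is.na(draws)),
       reliable = mean(!is.na(draws)) >= 0.5, B = B)
}

#' Evaluate a fitted SWF
#'
#' `predict(fit, t)` returns `u(t) = exp(ln_alpha1) * exp(b*t) * t^a`.
#'
#' @param object a `pto_swf` fit.
#' @param t health gains in years (> 0).
#' @param deriv 0 for `u(t)`, 2 for `u''(t)`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.pto_swf <- function(object, t, deriv = 0, ...) {
  swf_curve(object$coefficients, t, deriv)
}

swf_curve <- function(coefs, t, deriv = 0) {
  if (any(t <= 0)) stop("t must be positive")
  b <- coefs[["b_t"]]; a <- coefs[["a3"]]
  u <- exp(coefs[["ln_alpha1"]]) * exp(b * t) * t^a
  if (deriv == 0) u
  else if (deriv == 1) u * (b + a / t)
  else if (deriv == 2) u * ((b + a / t)^2 - a / t^2)
  else stop("deriv must be 0, 1 or 2")
}

#' @export
coef.pto_swf <- function(object, ...) object$coefficients

#' @export
residuals.pto_swf <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.pto_swf <- function(object, ...) stats::fitted(object$lm)

#' @export
print.pto_swf <- function(x, digits = 3, ...) {
  cat("Social welfare function fit: u(t) = a1 * exp(b*t) * t^a\n")
  cat(sprintf("  observations: %d (%d respondents)\n", x$n_obs, x$n_respondents))
  co <- x$coefficients
  cat(sprintf("  a1 = %.*f   b = %.*f   a = %.*f   adj R2 = %.*f\n",
              digits, exp(co[["ln_alpha1"]]), digits, co[["b_t"]],
              digits, co[["a3"]], digits, x$r2_adj))
  if (is.na(x$threshold)) {
    cat("  threshold: none (u'' does not change sign in the interval)\n")
  } else {
    cat(sprintf("  threshold: %.*f years (%s)\n", digits, x$threshold,
                x$threshold_direction))
    if (!is.null(x$ci))
      cat(sprintf("  %d%% percentile bootstrap CI: [%.*f, %.*f] (B = %d, %.1f%% degenerate%s)\n",
                  round(100 * x$level), digits, x$ci[1], digits, x$ci[2],
                  x$boot$B, 100 * x$boot$frac_degenerate,
                  if (x$boot$reliable) "" else "; UNRELIABLE"))
  }
  invisible(x)
}

#' @export
summary.pto_swf <- function(object, ...) {
  s <- summary(object$lm)
  tab <- s$coefficients
  rownames(tab) <- c("ln a1 (constant)", "t", "ln t")
  out <- list(coefficients = tab, r2_adj = s$adj.r.squared,
              n_obs = object$n_obs, n_respondents = object$n_respondents,
              threshold = object$threshold,
              threshold_direction = object$threshold_direction,
              ci = object$ci, level = object$level, boot = object$boot)
  class(out) <- "summary.pto_swf"
  out
}

#' @export
print.summary.pto_swf <- function(x, digits = 4, ...) {
  cat("ln u(t) = ln(a1) + b*t + a*ln(t), ordinary least squares\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nAdjusted R-squared: %.3f on %d observations (%d respondents)\n",
              x$r2_adj, x$n_obs, x$n_respondents))
  if (!is.na(x$threshold))
    cat(sprintf("Threshold: %.3f years (%s)\n", x$threshold, x$threshold_direction))
  if (!is.null(x$ci))
    cat(sprintf("%d%% percentile bootstrap CI: [%.3f, %.3f]\n",
                round(100 * x$level), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Plot a fitted SWF
#'
#' Two panels: the fitted social-value curve `u(t)` and its second
#' derivative `u''(t)`, with the threshold marked where present.
#'
#' @param x a `pto_swf` fit.
#' @param t_range range of gains to draw, years.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pto_swf <- function(x, t_range = c(0.2, 55), ...) {
  ts <- seq(t_range[1], t_range[2], length.out = 400)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(ts, predict(x, ts), type = "l", xlab = "t (years)",
                 ylab = "u(t)", main = "Social value", ...)
  graphics::plot(ts, predict(x, ts, deriv = 2), type = "l",
                 xlab = "t (years)", ylab = "u''(t)",
                 main = "Second derivative", ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.na(x$threshold)) graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
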