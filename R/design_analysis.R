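#' JZS Bayes factor for a two-sample t statistic
#'
#' The default Bayesian two-sample t-test: the standardized group difference
#' `delta` has a Cauchy prior with scale `r` under H1 and is zero under H0.
#' Given the pooled-variance t statistic with `n1 + n2 - 2` degrees of
#' freedom and effective sample size `n1 * n2 / (n1 + n2)`, the Bayes factor
#' is the prior-averaged noncentral-t likelihood divided by the central-t
#' likelihood, computed by adaptive one-dimensional quadrature over the
#' prior.
#'
#' With `alternative = "two.sided"` the prior is the full symmetric Cauchy,
#' so the Bayes factor depends on `t` only through `|t|`. With
#' `alternative = "greater"` the prior is the half-Cauchy on positive
#' effects (the directional test); negative t then tells against H1.
#'
#' @param t_statistic Observed two-sample t statistic (pooled variance).
#' @param n1,n2 Group sizes (>= 2).
#' @param prior_scale_r Cauchy scale of the effect-size prior (> 0);
#'   `sqrt(2)/2` is the conventional default.
#' @param alternative `"greater"` (directional half-Cauchy, the default) or
#'   `"two.sided"` (symmetric Cauchy).
#' @return The Bayes factor BF10 (positive scalar).
#' @examples
#' jzs_bf10(2.0, 36, 36)
#' jzs_bf10(0, 36, 36, alternative = "two.sided") # < 1: null data favor H0
#' @export
jzs_bf10 <- function(t_statistic, n1, n2, prior_scale_r = sqrt(2) / 2,
                     alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(t_statistic)) stop("'t_statistic' must be finite")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (!is.finite(prior_scale_r) || prior_scale_r <= 0)
    stop("'prior_scale_r' must be positive")
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)

  # Substituting delta = r * u puts the prior on a fixed scale, so the
  # adaptive quadrature stays well-conditioned for any r. dt(x, df, ncp)
  # warns about precision at extreme noncentralities; the quadrature
  # tolerance dominates that residual error.
  integrand <- function(u) {
    ncp <- prior_scale_r * u * sqrt(n_eff)
    suppressWarnings(stats::dt(t_statistic, nu, ncp = ncp)) *
      stats::dcauchy(u, 0, 1)
  }
  num <- tryCatch({
    if (alternative == "greater")
      2 * stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                           stop.on.error = TRUE)$value
    else
      stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-8,
                       stop.on.error = TRUE)$value
  }, error = function(e) {
    stop(errorCondition(
      sprintf("marginal-likelihood integration failed (t = %g, nu = %g, r = %g): %s",
              t_statistic, nu, prior_scale_r, conditionMessage(e)),
      class = "sevbf_numerical_error"))
  })
  num / stats::dt(t_statistic, nu)
}

#' Bayes Factor Design Analysis specification
#'
#' Settings for a fixed-n Monte-Carlo design analysis of a two-sample
#' Bayes-factor t-test: how likely is the planned experiment to deliver
#' evidence for the true hypothesis, inconclusive evidence, or misleading
#' evidence for the false one?
#'
#' @param n_per_group Group size (>= 2).
#' @param effect_size_d True standardized mean difference generating the
#'   data (`d = 0` examines behaviour when H0 is true).
#' @param prior_scale_r Cauchy prior scale for the Bayes factor.
#' @param upper_threshold,lower_threshold Evidence boundaries: BF above the
#'   upper threshold counts as evidence for H1, below the lower as evidence
#'   for H0, in between as inconclusive. Must satisfy `0 < L <= 1 <= U`.
#' @param n_sims Number of simulated experiments (>= 1).
#' @param seed RNG seed (or NULL to use the current RNG state).
#' @param alternative Sidedness of the Bayes factor, see [jzs_bf10()].
#' @return An object of class `bfda_spec`.
#' @export
bfda_spec <- function(n_per_group, effect_size_d,
                      prior_scale_r = sqrt(2) / 2,
                      upper_threshold = 3, lower_threshold = 1 / 3,
                      n_sims = 10000, seed = NULL,
                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_per_group < 2 || n_per_group != round(n_per_group))
    stop("'n_per_group' must be an integer >= 2")
  if (!is.finite(effect_size_d)) stop("'effect_size_d' must be finite")
  if (!is.finite(prior_scale_r) || prior_scale_r <= 0)
    stop("'prior_scale_r' must be positive")
  if (!(lower_threshold > 0 && lower_threshold <= 1 &&
        upper_threshold >= 1 && upper_threshold >= lower_threshold))
    stop("thresholds must satisfy 0 < L <= 1 <= U")
  if (n_sims < 1 || n_sims != round(n_sims))
    stop("'n_sims' must be an integer >= 1")
  structure(
    list(n_per_group = as.integer(n_per_group),
         effect_size_d = effect_size_d, prior_scale_r = prior_scale_r,
         upper_threshold = upper_threshold,
         lower_threshold = lower_threshold,
         n_sims = as.integer(n_sims), seed = seed,
         alternative = alternative),
    class = "bfda_spec"
  )
}

#' Monte-Carlo Bayes Factor Design Analysis
#'
#' Simulates the planned experiment `n_sims` times: two groups of
#' `n_per_group` observations are drawn from `Normal(0, 1)` and
#' `Normal(d, 1)`, the pooled two-sample t statistic is computed, the JZS
#' Bayes factor is evaluated, and the result is classified against the
#' evidence thresholds (strictly above U: evidence for H1; strictly below
#' L: evidence for H0 — misleading when `d > 0`; otherwise inconclusive).
#' Rates carry binomial Monte-Carlo standard errors and the three always
#' sum to one.
#'
#' @param spec A [bfda_spec()].
#' @return An object of class `bfda_result`: `rate_evidence_H1`,
#'   `rate_inconclusive`, `rate_misleading_H0`, matching `mc_standard_errors`
#'   (named vector), `bf_samples`, and the `spec`.
#' @examples
#' \donttest{
#' simulate_bfda(bfda_spec(36, 0.4, n_sims = 1000, seed = 1))
#' }
#' @export
simulate_bfda <- function(spec) {
  stopifnot(inherits(spec, "bfda_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_per_group
  bf <- vapply(seq_len(spec$n_sims), function(i) {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n, mean = spec$effect_size_d)
    sp2 <- ((n - 1) * stats::var(x) + (n - 1) * stats::var(y)) / (2 * n - 2)
    t_stat <- (mean(y) - mean(x)) / sqrt(sp2 * (2 / n))
    jzs_bf10(t_stat, n, n, spec$prior_scale_r, spec$alternative)
  }, numeric(1))

  r_h1 <- mean(bf > spec$upper_threshold)
  r_h0 <- mean(bf < spec$lower_threshold)
  r_inc <- 1 - r_h1 - r_h0
  se <- function(p) sqrt(p * (1 - p) / spec$n_sims)
  structure(
    list(rate_evidence_H1 = r_h1,
         rate_inconclusive = r_inc,
         rate_misleading_H0 = r_h0,
         mc_standard_errors = c(evidence_H1 = se(r_h1),
                                inconclusive = se(r_inc),
                                misleading_H0 = se(r_h0)),
         bf_samples = bf, spec = spec),
    class = "bfda_result"
  )
}

#' @export
print.bfda_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "BFDA: n = %d/group, d = %g, r = %.4g, thresholds (%.4g, %.4g), %d sims\n",
    s$n_per_group, s$effect_size_d, s$prior_scale_r,
    s$upper_threshold, s$lower_threshold, s$n_sims))
  row <- function(label, rate, se)
    cat(sprintf("  %-30s %5.1f%% (se %.2f pp)\n", label, 100 * rate, 100 * se))
  row(sprintf("evidence for H1 (BF > %.3g):", s$upper_threshold),
      x$rate_evidence_H1, x$mc_standard_errors["evidence_H1"])
  row("inconclusive:", x$rate_inconclusive, x$mc_standard_errors["inconclusive"])
  row(sprintf("evidence for H0 (BF < %.3g):", s$lower_threshold),
      x$rate_misleading_H0, x$mc_standard_errors["misleading_H0"])
  invisible(x)
}

#' Design-analysis rates across a grid of sample sizes
#'
#' Runs [simulate_bfda()] for each group size in `n_grid` with otherwise
#' identical settings and a shared seed stream, for sample-size planning.
#'
#' @param spec A [bfda_spec()]; its `n_per_group` is overridden per grid
#'   point.
#' @param n_grid Vector of group sizes.
#' @return A data frame with one row per grid point: `n_per_group`,
#'   `rate_evidence_H1`, `rate_inconclusive`, `rate_misleading_H0`.
#' @export
rate_curve <- function(spec, n_grid) {
  stopifnot(inherits(spec, "bfda_spec"))
  if (length(n_grid) == 0) stop("'n_grid' must be non-empty")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- lapply(n_grid, function(n) {
    s <- spec
    s$n_per_group <- as.integer(n)
    s$seed <- NULL  # one shared stream across the grid
    res <- simulate_bfda(s)
    data.frame(n_per_group = n,
               rate_evidence_H1 = res$rate_evidence_H1,
               rate_inconclusive = res$rate_inconclusive,
               rate_misleading_H0 = res$rate_misleading_H0)
  })
  do.call(rbind, rows)
}
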