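#' Interval-constrained hypothesis on two binomial success rates
#'
#' Defines a hypothesis that restricts the success rates `theta_A`, `theta_B`
#' of two independent treatments to closed sub-intervals of \[0, 1\]. The
#' unconstrained special case `[0,1] x [0,1]` is the encompassing model, from
#' which every constrained hypothesis inherits its (truncated-uniform) prior.
#' The product of the interval lengths is the hypothesis's prior mass under
#' the encompassing uniform prior — its lack of specificity.
#'
#' @param region_A,region_B Length-2 numeric vectors `c(lo, hi)` with
#'   `0 <= lo <= hi <= 1`, the allowed range of each arm's success rate.
#' @param label Optional text label.
#' @return An object of class `interval_hypothesis`.
#' @examples
#' h_vague    <- interval_hypothesis(c(0, 0.5), c(0.5, 1), "H_v")
#' h_specific <- interval_hypothesis(c(0.2, 0.3), c(0.7, 0.8), "H_s")
#' h_enc      <- encompassing_hypothesis()
#' prior_region_mass(h_specific) # 0.01
#' @export
interval_hypothesis <- function(region_A, region_B, label = "H") {
  check_region <- function(r, name) {
    if (length(r) != 2 || anyNA(r) || !is.numeric(r))
      stop(sprintf("'%s' must be a numeric c(lo, hi)", name))
    if (r[1] < 0 || r[2] > 1 || r[1] > r[2])
      stop(sprintf("'%s' must satisfy 0 <= lo <= hi <= 1", name))
    as.numeric(r)
  }
  structure(
    list(label = as.character(label),
         region_A = check_region(region_A, "region_A"),
         region_B = check_region(region_B, "region_B")),
    class = "interval_hypothesis"
  )
}

#' @rdname interval_hypothesis
#' @export
encompassing_hypothesis <- function(label = "H_e") {
  interval_hypothesis(c(0, 1), c(0, 1), label)
}

#' @export
print.interval_hypothesis <- function(x, ...) {
  cat(sprintf("%s: theta_A in [%g, %g], theta_B in [%g, %g]  (prior mass %g)\n",
              x$label, x$region_A[1], x$region_A[2],
              x$region_B[1], x$region_B[2], prior_region_mass(x)))
  invisible(x)
}

#' Two-arm binomial design and outcome
#'
#' `binomial_design()` records the number of patients per treatment arm;
#' `binomial_outcome()` records the observed success counts.
#'
#' @param n_A,n_B Per-arm sample sizes (integers >= 1).
#' @param s_A,s_B Observed success counts, `0 <= s_i <= n_i`.
#' @param design The `binomial_design` the outcome belongs to.
#' @return Objects of class `binomial_design` / `binomial_outcome`.
#' @export
binomial_design <- function(n_A, n_B) {
  for (n in c(n_A, n_B))
    if (!is.finite(n) || n < 1 || n != round(n))
      stop("sample sizes must be integers >= 1")
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B)),
            class = "binomial_design")
}

#' @rdname binomial_design
#' @export
binomial_outcome <- function(s_A, s_B, design) {
  stopifnot(inherits(design, "binomial_design"))
  if (!is.finite(s_A) || s_A != round(s_A) || s_A < 0 || s_A > design$n_A)
    stop("'s_A' must be an integer in [0, n_A]")
  if (!is.finite(s_B) || s_B != round(s_B) || s_B < 0 || s_B > design$n_B)
    stop("'s_B' must be an integer in [0, n_B]")
  structure(list(s_A = as.integer(s_A), s_B = as.integer(s_B),
                 design = design),
            class = "binomial_outcome")
}

#' Prior mass of an interval hypothesis under the encompassing prior
#'
#' The probability the uniform encompassing prior assigns to the hypothesis's
#' parameter region: the product of its interval lengths. Its reciprocal caps
#' the Bayes factor the hypothesis can ever earn against the encompassing
#' model, so this number is the hypothesis's specificity.
#'
#' @param h An [interval_hypothesis()].
#' @return A probability in (0, 1\].
#' @export
prior_region_mass <- function(h) {
  stopifnot(inherits(h, "interval_hypothesis"))
  len <- c(diff(h$region_A), diff(h$region_B))
  if (any(len == 0))
    stop("degenerate hypothesis: zero-length interval (point hypotheses not supported)")
  prod(len)
}

#' Posterior mass of an interval hypothesis given a two-arm outcome
#'
#' Under the uniform encompassing prior, each arm's posterior is
#' `Beta(s_i + 1, n_i - s_i + 1)`; by independence the posterior mass of the
#' region is the product of the per-arm Beta-CDF differences over the
#' hypothesis's intervals.
#'
#' @param h An [interval_hypothesis()].
#' @param outcome A [binomial_outcome()].
#' @return A probability in \[0, 1\].
#' @export
posterior_region_mass <- function(h, outcome) {
  stopifnot(inherits(h, "interval_hypothesis"),
            inherits(outcome, "binomial_outcome"))
  d <- outcome$design
  beta_mass <- function(region, s, n)
    stats::pbeta(region[2], s + 1, n - s + 1) -
      stats::pbeta(region[1], s + 1, n - s + 1)
  beta_mass(h$region_A, outcome$s_A, d$n_A) *
    beta_mass(h$region_B, outcome$s_B, d$n_B)
}

#' Encompassing-prior Bayes factor for an interval hypothesis
#'
#' The Bayes factor of a constrained hypothesis against the encompassing
#' model equals the ratio of the posterior to the prior mass of its
#' parameter region — equivalently the ratio of the two marginal
#' likelihoods. Both routes are computed; they must agree to 1e-6 relative
#' tolerance, which guards the implementation against itself.
#'
#' @param h An [interval_hypothesis()].
#' @param outcome A [binomial_outcome()].
#' @return An object of class `bf_result`: `bf`, `log_bf` (natural log),
#'   `prior_mass`, `posterior_mass`, `marginal_constrained`,
#'   `marginal_encompassing`, and `label`. A numerically zero posterior mass
#'   yields `bf = 0` with `log_bf = -Inf` and `underflow = TRUE` rather than
#'   an error.
#' @examples
#' d <- binomial_design(20, 20)
#' y <- binomial_outcome(5, 15, d)
#' bf_vs_encompassing(interval_hypothesis(c(0.2, 0.3), c(0.7, 0.8), "H_s"), y)
#' @export
bf_vs_encompassing <- function(h, outcome) {
  stopifnot(inherits(h, "interval_hypothesis"),
            inherits(outcome, "binomial_outcome"))
  pm <- prior_region_mass(h)
  post <- posterior_region_mass(h, outcome)
  bf <- post / pm

  d <- outcome$design
  m_h <- predictive_pmf_point(h, outcome)
  m_e <- predictive_pmf_point(encompassing_hypothesis(), outcome)
  if (m_e > 0 && bf > 0) {
    rel <- abs(bf - m_h / m_e) / bf
    if (is.finite(rel) && rel > 1e-6)
      stop("internal inconsistency: mass-ratio and marginal-likelihood routes disagree")
  }

  structure(
    list(bf = bf, log_bf = if (bf > 0) log(bf) else -Inf,
         prior_mass = pm, posterior_mass = post,
         marginal_constrained = m_h, marginal_encompassing = m_e,
         underflow = bf == 0, label = h$label),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF(%s vs encompassing) = %.4g  (log BF = %.4g)\n",
              x$label, x$bf, x$log_bf))
  cat(sprintf("  prior mass %.4g, posterior mass %.4g\n",
              x$prior_mass, x$posterior_mass))
  invisible(x)
}

# Marginal likelihood p(y | H) of one lattice point: per arm,
# integral of the binomial likelihood over the truncated-uniform prior,
# which reduces to a Beta-CDF difference / ((n + 1) * interval length).
predictive_pmf_point <- function(h, outcome) {
  d <- outcome$design
  arm_marginal_pmf(h$region_A, d$n_A)[outcome$s_A + 1] *
    arm_marginal_pmf(h$region_B, d$n_B)[outcome$s_B + 1]
}

# Prior-predictive pmf of one arm's success count on 0:n, for a
# truncated-uniform prior on [lo, hi]. Exact: choose(n, s) * B(s+1, n-s+1)
# = 1 / (n + 1) makes the integral a regularized incomplete-beta difference.
arm_marginal_pmf <- function(region, n) {
  lo <- region[1]; hi <- region[2]
  s <- 0:n
  if (hi == lo) stop("degenerate hypothesis: zero-length interval")
  (stats::pbeta(hi, s + 1, n - s + 1) - stats::pbeta(lo, s + 1, n - s + 1)) /
    ((n + 1) * (hi - lo))
}

#' Prior-predictive distribution of a two-arm binomial design
#'
#' The data a hypothesis predicts: for each arm, the success-count pmf after
#' integrating the binomial likelihood over the hypothesis's
#' truncated-uniform prior (computed exactly via regularized
#' incomplete-beta differences, no Monte Carlo); the joint pmf on the
#' `(n_A + 1) x (n_B + 1)` outcome lattice is the product of the arm
#' marginals, since the arms are independent.
#'
#' @param h An [interval_hypothesis()].
#' @param design A [binomial_design()].
#' @return An object of class `predictive_distribution`: `joint` (matrix,
#'   rows `s_A = 0:n_A`, columns `s_B = 0:n_B`), `marginal_A`, `marginal_B`,
#'   `design`, `label`.
#' @export
prior_predictive <- function(h, design) {
  stopifnot(inherits(h, "interval_hypothesis"),
            inherits(design, "binomial_design"))
  pA <- arm_marginal_pmf(h$region_A, design$n_A)
  pB <- arm_marginal_pmf(h$region_B, design$n_B)
  joint <- outer(pA, pB)
  dimnames(joint) <- list(s_A = 0:design$n_A, s_B = 0:design$n_B)
  structure(
    list(joint = joint, marginal_A = pA, marginal_B = pB,
         design = design, label = h$label),
    class = "predictive_distribution"
  )
}

#' @export
print.predictive_distribution <- function(x, ...) {
  cat(sprintf("Prior-predictive distribution under %s (n_A = %d, n_B = %d)\n",
              x$label, x$design$n_A, x$design$n_B))
  cat("  arm A marginal pmf:\n")
  print(round(x$marginal_A, 4))
  invisible(x)
}

# Smallest set of support points, added in decreasing pmf order, whose mass
# reaches `coverage`; pmf ties at the inclusion boundary enter together.
discrete_hdr <- function(pmf, coverage) {
  ord <- order(pmf, decreasing = TRUE)
  cum <- cumsum(pmf[ord])
  k <- which(cum >= coverage)[1]
  if (is.na(k)) k <- length(pmf)
  boundary <- pmf[ord[k]]
  # include everything at least as probable as the last point admitted
  which(pmf >= boundary)
}

#' Outcomes outside a predictive highest-density region
#'
#' For each arm's prior-predictive pmf, finds the complement of the
#' discrete highest-density region (HDR) at the given coverage: the
#' outcomes the hypothesis effectively rules out. The HDR is the smallest
#' set of support points, taken in decreasing probability order, whose
#' total mass reaches the coverage; tied probabilities are included
#' together. If outcomes outside the HDR are plausible a priori, the
#' hypothesis is exposed to refutation — a precondition for a severe test.
#'
#' @param h An [interval_hypothesis()].
#' @param design A [binomial_design()].
#' @param coverage HDR probability mass, strictly between 0 and 1.
#' @return A list with integer vectors `arm_A` and `arm_B`: the success
#'   counts outside each arm's HDR.
#' @examples
#' h_v <- interval_hypothesis(c(0, 0.5), c(0.5, 1), "H_v")
#' hdr_complement(h_v, binomial_design(20, 20), 0.99)
#' # arm A: 14..20, arm B: 0..6
#' @export
hdr_complement <- function(h, design, coverage) {
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("'coverage' must lie strictly between 0 and 1")
  pred <- prior_predictive(h, design)
  comp <- function(pmf) {
    inside <- discrete_hdr(pmf, coverage)
    setdiff(seq_along(pmf), inside) - 1L
  }
  list(arm_A = comp(pred$marginal_A), arm_B = comp(pred$marginal_B))
}

#' Bayes-factor surface over all possible outcomes
#'
#' Evaluates [bf_vs_encompassing()] at every point of the
#' `(n_A + 1) x (n_B + 1)` outcome lattice, showing which data would count
#' as evidence for the hypothesis and how strongly. No entry can exceed
#' `1 / prior_region_mass(h)`.
#'
#' @param h An [interval_hypothesis()].
#' @param design A [binomial_design()].
#' @return A matrix of Bayes factors, rows `s_A = 0:n_A`, columns
#'   `s_B = 0:n_B`.
#' @export
bf_lattice <- function(h, design) {
  stopifnot(inherits(h, "interval_hypothesis"),
            inherits(design, "binomial_design"))
  pm <- prior_region_mass(h)
  post_A <- vapply(0:design$n_A, function(s)
    stats::pbeta(h$region_A[2], s + 1, design$n_A - s + 1) -
      stats::pbeta(h$region_A[1], s + 1, design$n_A - s + 1), numeric(1))
  post_B <- vapply(0:design$n_B, function(s)
    stats::pbeta(h$region_B[2], s + 1, design$n_B - s + 1) -
      stats::pbeta(h$region_B[1], s + 1, design$n_B - s + 1), numeric(1))
  m <- outer(post_A, post_B) / pm
  dimnames(m) <- list(s_A = 0:design$n_A, s_B = 0:design$n_B)
  m
}

#' Verbal classification of a Bayes factor
#'
#' Maps a Bayes factor to the conventional evidence categories of Lee and
#' Wagenmakers (adjusted from Jeffreys): anecdotal, moderate, strong, very
#' strong or extreme evidence for H1 (BF above 1) or for H0 (below 1).
#'
#' @param bf A positive Bayes factor (BF10).
#' @return A character label.
#' @examples
#' classify_bf(16.53) # "Strong evidence for H1"
#' @export
classify_bf <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1 || !is.finite(bf) || bf <= 0)
    stop("'bf' must be a single positive number")
  if (bf == 1) return("No evidence for either hypothesis")
  if (bf > 1) {
    if (bf > 100) "Extreme evidence for H1"
    else if (bf > 30) "Very strong evidence for H1"
    else if (bf > 10) "Strong evidence for H1"
    else if (bf > 3) "Moderate evidence for H1"
    else "Anecdotal evidence for H1"
  } else {
    if (bf < 1 / 100) "Extreme evidence for H0"
    else if (bf < 1 / 30) "Very strong evidence for H0"
    else if (bf < 1 / 10) "Strong evidence for H0"
    else if (bf < 1 / 3) "Moderate evidence for H0"
    else "Anecdotal evidence for H0"
  }
}
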