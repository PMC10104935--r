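#' Mixture marginal of constrained and encompassing predictions
#'
#' The marginal distribution of the data before the experiment, when the
#' constrained hypothesis and the encompassing model both have prior
#' probability: `p(y) = w_h * p(y | H) + w_e * p(y | H_e)`. This is the
#' weighting distribution in the expected-evidential-value calculation.
#'
#' @param h An [interval_hypothesis()].
#' @param design A [binomial_design()].
#' @param weights Length-2 nonnegative vector `c(w_constrained,
#'   w_encompassing)` summing to 1 (default equal weights).
#' @return A `predictive_distribution` whose joint pmf is the convex
#'   combination of the two prior predictives.
#' @export
mixture_marginal <- function(h, design, weights = c(0.5, 0.5)) {
  weights <- check_weights(weights)
  p_h <- prior_predictive(h, design)
  p_e <- prior_predictive(encompassing_hypothesis(), design)
  joint <- weights[1] * p_h$joint + weights[2] * p_e$joint
  structure(
    list(joint = joint,
         marginal_A = rowSums(joint), marginal_B = colSums(joint),
         design = design,
         label = sprintf("%g %s + %g H_e", weights[1], h$label, weights[2])),
    class = "predictive_distribution"
  )
}

check_weights <- function(weights) {
  if (length(weights) != 2 || anyNA(weights) || any(weights < 0))
    stop("'weights' must be two nonnegative numbers")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1")
  as.numeric(weights)
}

#' Expected absolute log Bayes factor of a design
#'
#' The pre-experimental evidential value of testing an interval hypothesis
#' against the encompassing model with a given two-arm design:
#' `E_y[ |log BF(y)| ]`, the average strength of evidence — for or against —
#' the experiment is expected to deliver, where `y` ranges over the full
#' `(n_A + 1) x (n_B + 1)` outcome lattice and is weighted by the mixture
#' marginal `p(y) = w_h p(y|H) + w_e p(y|H_e)`. The sum is exact (no Monte
#' Carlo) and uses the natural logarithm. `|log BF|` is evaluated in
#' log-space from log marginal likelihoods, so outcomes whose Bayes factor
#' underflows to zero still contribute a finite term whenever the true
#' Bayes factor is positive.
#'
#' A design with low expected evidential value cannot probe the hypothesis
#' severely no matter how the data come out.
#'
#' @param h An [interval_hypothesis()].
#' @param design A [binomial_design()].
#' @param weights Prior model probabilities `c(p(H), p(H_e))`, summing to 1.
#' @return An object of class `evidential_value_result`: `expectation`
#'   (nonnegative, in nats), `expected_log_bf` (signed mean, for the Jensen
#'   bound), and `per_outcome`, a data frame with columns `s_A`, `s_B`,
#'   `p_y`, `log_bf`, `abs_log_bf`.
#' @examples
#' h_s <- interval_hypothesis(c(0.2, 0.3), c(0.7, 0.8), "H_s")
#' expected_abs_log_bf(h_s, binomial_design(20, 20))$expectation # 6.32
#' @export
expected_abs_log_bf <- function(h, design, weights = c(0.5, 0.5)) {
  stopifnot(inherits(h, "interval_hypothesis"),
            inherits(design, "binomial_design"))
  weights <- check_weights(weights)
  prior_region_mass(h)  # rejects degenerate hypotheses up front

  log_pA_h <- log_arm_marginal_pmf(h$region_A, design$n_A)
  log_pB_h <- log_arm_marginal_pmf(h$region_B, design$n_B)
  log_pA_e <- log_arm_marginal_pmf(c(0, 1), design$n_A)
  log_pB_e <- log_arm_marginal_pmf(c(0, 1), design$n_B)

  # log BF at each lattice point = log p(y|H) - log p(y|H_e)
  log_bf <- outer(log_pA_h - log_pA_e, log_pB_h - log_pB_e, `+`)
  p_h <- exp(outer(log_pA_h, log_pB_h, `+`))
  p_e <- exp(outer(log_pA_e, log_pB_e, `+`))
  p_y <- weights[1] * p_h + weights[2] * p_e

  # p(y) = 0 exactly only where both components vanish; such outcomes
  # contribute nothing regardless of log BF
  term <- ifelse(p_y > 0, p_y * abs(log_bf), 0)

  grid <- expand.grid(s_A = 0:design$n_A, s_B = 0:design$n_B)
  structure(
    list(expectation = sum(term),
         expected_log_bf = sum(ifelse(p_y > 0, p_y * log_bf, 0)),
         per_outcome = data.frame(grid, p_y = as.vector(p_y),
                                  log_bf = as.vector(log_bf),
                                  abs_log_bf = abs(as.vector(log_bf))),
         weights = weights, label = h$label),
    class = "evidential_value_result"
  )
}

# log of arm_marginal_pmf, via log-CDF differences where possible; falls
# back on the direct pmf log (the beta-CDF difference is never negative)
log_arm_marginal_pmf <- function(region, n) {
  p <- arm_marginal_pmf(region, n)
  log(p)
}

#' @export
print.evidential_value_result <- function(x, ...) {
  cat(sprintf("Expected |log BF| for %s vs encompassing: %.4f nats\n",
              x$label, x$expectation))
  cat(sprintf("  (mixture weights %g / %g; signed mean log BF %.4f)\n",
              x$weights[1], x$weights[2], x$expected_log_bf))
  invisible(x)
}

#' Update prior odds by a Bayes factor
#'
#' Posterior odds are prior odds times the Bayes factor.
#'
#' @param prior_odds Positive prior odds.
#' @param bf Positive Bayes factor.
#' @return The posterior odds.
#' @export
update_odds <- function(prior_odds, bf) {
  if (!is.finite(prior_odds) || prior_odds <= 0)
    stop("'prior_odds' must be positive")
  if (!is.finite(bf) || bf <= 0)
    stop("'bf' must be positive")
  prior_odds * bf
}

#' Space of binary predictions a theory constrains
#'
#' Describes a theory's prediction about a sequence of binary observation
#' slots (e.g. rain / no rain on each of 30 days) so its empirical content
#' can be counted. Three predicate kinds are supported in closed form:
#' `"exact_count"` (rain on exactly `k` unspecified days — `choose(n, k)`
#' consistent sequences), `"specified"` (rain on exactly the listed days and
#' no others — one consistent sequence), and `"all"` (a vacuous theory that
#' allows everything). A custom `predicate` function over 0/1 vectors is
#' evaluated by full enumeration, feasible only for `n_slots <= 25`.
#'
#' @param n_slots Number of binary slots (>= 1).
#' @param kind One of `"exact_count"`, `"specified"`, `"all"`,
#'   `"predicate"`.
#' @param k Number of positive slots (for `"exact_count"`).
#' @param days Integer positions of the positive slots (for `"specified"`).
#' @param predicate A function taking a 0/1 vector of length `n_slots` and
#'   returning TRUE if the sequence is allowed (for `"predicate"`).
#' @return An object of class `prediction_space`.
#' @export
prediction_space <- function(n_slots,
                             kind = c("exact_count", "specified", "all",
                                      "predicate"),
                             k = NULL, days = NULL, predicate = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(n_slots) || n_slots < 1 || n_slots != round(n_slots))
    stop("'n_slots' must be an integer >= 1")
  n_slots <- as.integer(n_slots)
  if (kind == "exact_count") {
    if (is.null(k) || k < 0 || k > n_slots || k != round(k))
      stop("'k' must be an integer in [0, n_slots]")
  }
  if (kind == "specified") {
    if (is.null(days) || anyNA(days) ||
        any(days < 1 | days > n_slots | days != round(days)) ||
        anyDuplicated(days))
      stop("'days' must be distinct integer positions in [1, n_slots]")
  }
  if (kind == "predicate") {
    if (!is.function(predicate)) stop("'predicate' must be a function")
    if (n_slots > 25)
      stop("enumeration over more than 25 slots is not feasible; ",
           "use a closed-form kind")
  }
  structure(list(n_slots = n_slots, kind = kind, k = k,
                 days = days, predicate = predicate),
            class = "prediction_space")
}

#' Empirical content of a prediction
#'
#' Counts how many of the `2^n` possible binary sequences a theory's
#' prediction allows. The smaller the ratio of consistent sequences to all
#' sequences, the more the theory forbids and the more impressive a
#' confirmed prediction is. Counts are exact (they stay well below 2^53,
#' so double arithmetic is integer-exact).
#'
#' @param space A [prediction_space()].
#' @return A list with `consistent` (number of allowed sequences), `total`
#'   (`2^n_slots`), and `ratio`.
#' @examples
#' # rain on exactly 3 of 30 days: choose(30, 3) = 4060 of 2^30 sequences
#' empirical_content(prediction_space(30, "exact_count", k = 3))
#' @export
empirical_content <- function(space) {
  stopifnot(inherits(space, "prediction_space"))
  n <- space$n_slots
  total <- 2^n
  consistent <- switch(
    space$kind,
    exact_count = choose(n, space$k),
    specified = 1,
    all = total,
    predicate = {
      count <- 0
      for (i in 0:(2^n - 1)) {
        bits <- as.integer(intToBits(i))[seq_len(n)]
        if (isTRUE(space$predicate(bits))) count <- count + 1
      }
      count
    }
  )
  list(consistent = consistent, total = total, ratio = consistent / total)
}
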