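test_that("prior region mass is the product of interval lengths", {
  expect_equal(prior_region_mass(h_vague()), 0.25)
  expect_equal(prior_region_mass(h_specific()), 0.01)
  expect_equal(prior_region_mass(encompassing_hypothesis()), 1)
  expect_error(prior_region_mass(interval_hypothesis(c(0.3, 0.3), c(0, 1))),
               "degenerate")
})

test_that("posterior region mass comes from the per-arm Beta posteriors", {
  # H_e always has full posterior mass
  expect_equal(posterior_region_mass(encompassing_hypothesis(), outcome_20()), 1)
  # independent quadrature of the Beta(6,16) x Beta(16,6) posterior density
  post_quad <- function(h, outcome) {
    d <- outcome$design
    arm <- function(region, s, n)
      integrate(function(th) dbeta(th, s + 1, n - s + 1),
                region[1], region[2], rel.tol = 1e-10)$value
    arm(h$region_A, outcome$s_A, d$n_A) * arm(h$region_B, outcome$s_B, d$n_B)
  }
  expect_equal(posterior_region_mass(h_vague(), outcome_20()),
               post_quad(h_vague(), outcome_20()), tolerance = 1e-8)
  expect_equal(posterior_region_mass(h_specific(), outcome_4()),
               post_quad(h_specific(), outcome_4()), tolerance = 1e-8)
})

test_that("encompassing-prior Bayes factors reproduce the four treatment scenarios", {
  cases <- list(
    list(h = h_specific(), y = outcome_20(), bf = 16.53),
    list(h = h_specific(), y = outcome_4(),  bf = 4.37),
    list(h = h_vague(),    y = outcome_20(), bf = 3.89),
    list(h = h_vague(),    y = outcome_4(),  bf = 2.64)
  )
  for (case in cases) {
    r <- bf_vs_encompassing(case$h, case$y)
    expect_equal(r$bf, case$bf, tolerance = 0.005 / case$bf)
    expect_equal(r$log_bf, log(r$bf))
    expect_equal(r$bf, r$posterior_mass / r$prior_mass)
  }
  # a model against itself carries no evidence
  expect_equal(bf_vs_encompassing(encompassing_hypothesis(), outcome_20())$bf, 1)
  # specific-beats-vague ordering when the data align with both
  expect_gt(cases[[1]]$bf, cases[[3]]$bf)
  expect_gt(cases[[2]]$bf, cases[[4]]$bf)
})

test_that("mass-ratio and marginal-likelihood routes agree on random instances", {
  set.seed(71)
  for (i in 1:25) {
    h <- random_hypothesis()
    y <- random_outcome()
    r <- bf_vs_encompassing(h, y)
    m_ratio <- quadrature_marginal(h, y) /
      quadrature_marginal(encompassing_hypothesis(), y)
    if (r$bf > 1e-12) {
      expect_equal(r$bf, m_ratio, tolerance = 1e-6)
    }
    # specificity bound: no outcome can earn more than 1 / prior mass
    expect_lte(r$bf, 1 / prior_region_mass(h) * (1 + 1e-12))
  }
})

test_that("Monte-Carlo marginal likelihood agrees with the closed form", {
  set.seed(19)
  h <- h_specific()
  y <- outcome_20()
  n_draws <- 1e5
  th_A <- runif(n_draws, h$region_A[1], h$region_A[2])
  th_B <- runif(n_draws, h$region_B[1], h$region_B[2])
  lik <- dbinom(y$s_A, y$design$n_A, th_A) * dbinom(y$s_B, y$design$n_B, th_B)
  mc <- mean(lik)
  mc_se <- sd(lik) / sqrt(n_draws)
  closed <- bf_vs_encompassing(h, y)$marginal_constrained
  expect_lt(abs(closed - mc), 3 * mc_se)
})

test_that("prior predictive pmfs are proper and match enumeration", {
  # uniform prior, one observation: Laplace's rule of succession
  pred <- prior_predictive(encompassing_hypothesis(), binomial_design(1, 1))
  expect_equal(pred$marginal_A, c(0.5, 0.5))
  expect_equal(sum(pred$joint), 1, tolerance = 1e-9)

  pred_s <- prior_predictive(h_specific(), design_20())
  expect_equal(sum(pred_s$joint), 1, tolerance = 1e-9)
  expect_equal(rowSums(pred_s$joint), pred_s$marginal_A, tolerance = 1e-12,
               ignore_attr = TRUE)
  # mode of arm A sits at 5 successes (rates near 0.25 out of 20)
  expect_equal(which.max(pred_s$marginal_A) - 1L, 5L)
  # per-point agreement with quadrature enumeration over the 21-point support
  for (s in 0:20) {
    direct <- integrate(function(th) dbinom(s, 20, th) / 0.1,
                        0.2, 0.3, rel.tol = 1e-10)$value
    expect_equal(pred_s$marginal_A[s + 1], direct, tolerance = 1e-8)
  }

  # the vague hypothesis barely predicts 14..20 successes in arm A
  pred_v <- prior_predictive(h_vague(), design_20())
  expect_lt(sum(pred_v$marginal_A[15:21]), 0.01)
})

test_that("HDR complements match the plausibility analysis of both hypotheses", {
  comp_v <- hdr_complement(h_vague(), design_20(), 0.99)
  expect_equal(comp_v$arm_A, 14:20)
  expect_equal(comp_v$arm_B, 0:6)

  # the minimal 99% HDR for the specific hypothesis is {1..10} (mass
  # 0.9903); S = 0 carries more mass than S = 11, so both sit outside
  comp_s <- hdr_complement(h_specific(), design_20(), 0.99)
  expect_equal(comp_s$arm_A, c(0, 11:20))

  # N = 1 under the encompassing prior: both outcomes tie at mass 1/2, so a
  # 50% HDR takes the full support and the complement is empty
  comp_e <- hdr_complement(encompassing_hypothesis(), binomial_design(1, 1), 0.5)
  expect_equal(comp_e$arm_A, integer(0))

  expect_error(hdr_complement(h_vague(), design_20(), 1), "coverage")
  expect_error(hdr_complement(h_vague(), design_20(), 0), "coverage")
})

test_that("HDRs hold the coverage and are minimal", {
  set.seed(5)
  for (i in 1:10) {
    h <- random_hypothesis()
    d <- binomial_design(sample(2:30, 1), sample(2:30, 1))
    coverage <- runif(1, 0.5, 0.995)
    pred <- prior_predictive(h, d)
    comp <- hdr_complement(h, d, coverage)
    inside <- setdiff(0:d$n_A, comp$arm_A)
    mass <- sum(pred$marginal_A[inside + 1])
    expect_gte(mass, coverage)
    # dropping the least probable member (and its ties) must break coverage
    if (length(inside) > 0) {
      p_in <- pred$marginal_A[inside + 1]
      expect_lt(mass - sum(p_in[p_in == min(p_in)]), coverage)
    }
  }
})

test_that("the Bayes-factor lattice is bounded by the specificity", {
  lat_s <- bf_lattice(h_specific(), design_20())
  expect_equal(dim(lat_s), c(21, 21))
  expect_lte(max(lat_s), 100)
  expect_equal(lat_s["5", "15"],
               bf_vs_encompassing(h_specific(), outcome_20())$bf)

  lat_v <- bf_lattice(h_vague(), design_20())
  expect_equal(lat_v["5", "15"], 3.89, tolerance = 2e-3)

  expect_true(all(bf_lattice(encompassing_hypothesis(), design_4()) == 1))
})

test_that("Bayes factors map onto the conventional evidence categories", {
  expect_equal(classify_bf(16.53), "Strong evidence for H1")
  expect_equal(classify_bf(150), "Extreme evidence for H1")
  expect_equal(classify_bf(50), "Very strong evidence for H1")
  expect_equal(classify_bf(4.37), "Moderate evidence for H1")
  expect_equal(classify_bf(2), "Anecdotal evidence for H1")
  expect_equal(classify_bf(1), "No evidence for either hypothesis")
  expect_equal(classify_bf(0.5), "Anecdotal evidence for H0")
  expect_equal(classify_bf(0.2), "Moderate evidence for H0")
  expect_equal(classify_bf(0.05), "Strong evidence for H0")
  expect_equal(classify_bf(0.02), "Very strong evidence for H0")
  expect_equal(classify_bf(0.001), "Extreme evidence for H0")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})

test_that("hypothesis and outcome constructors validate their inputs", {
  expect_error(interval_hypothesis(c(0.5, 0.2), c(0, 1)), "lo <= hi")
  expect_error(interval_hypothesis(c(-0.1, 0.5), c(0, 1)), "lo <= hi")
  expect_error(binomial_design(0, 5), ">= 1")
  d <- binomial_design(10, 10)
  expect_error(binomial_outcome(11, 5, d), "s_A")
  expect_error(binomial_outcome(5, -1, d), "s_B")
})
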