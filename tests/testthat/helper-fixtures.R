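# Worked-example fixtures shared across test files.

h_specific <- function() interval_hypothesis(c(0.2, 0.3), c(0.7, 0.8), "H_s")
h_vague <- function() interval_hypothesis(c(0.0, 0.5), c(0.5, 1.0), "H_v")

design_20 <- function() binomial_design(20, 20)
design_4 <- function() binomial_design(4, 4)

outcome_20 <- function() binomial_outcome(5, 15, design_20())
outcome_4 <- function() binomial_outcome(1, 3, design_4())

# Independent oracle: marginal likelihood p(s_A, s_B | H) by adaptive
# quadrature of the binomial likelihood against the truncated-uniform
# prior density, one integral per arm. Never reuses the package's
# incomplete-beta shortcut.
quadrature_marginal <- function(h, outcome) {
  d <- outcome$design
  arm <- function(region, s, n) {
    stats::integrate(function(th) stats::dbinom(s, n, th) / diff(region),
                     region[1], region[2], rel.tol = 1e-10)$value
  }
  arm(h$region_A, outcome$s_A, d$n_A) * arm(h$region_B, outcome$s_B, d$n_B)
}

# Independent oracle for the JZS numerator: fixed-grid trapezoid quadrature
# over a tanh-transformed effect axis (no adaptive machinery shared with
# the implementation).
trapezoid_jzs <- function(t_stat, n1, n2, r, alternative = "greater") {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  # delta = atanh-style stretch: delta in (-dmax, dmax) with fine spacing
  dmax <- 60 * r
  grid <- seq(if (alternative == "greater") 0 else -dmax, dmax,
              length.out = 400001)
  f <- suppressWarnings(stats::dt(t_stat, nu, ncp = grid * sqrt(n_eff))) *
    stats::dcauchy(grid, 0, r) * (if (alternative == "greater") 2 else 1)
  step <- grid[2] - grid[1]
  num <- step * (sum(f) - (f[1] + f[length(f)]) / 2)
  num / stats::dt(t_stat, nu)
}

random_hypothesis <- function() {
  rand_region <- function() sort(stats::runif(2))
  interval_hypothesis(rand_region(), rand_region(), "H_rand")
}

random_outcome <- function(n_max = 25) {
  n_A <- sample(1:n_max, 1)
  n_B <- sample(1:n_max, 1)
  binomial_outcome(sample(0:n_A, 1), sample(0:n_B, 1),
                   binomial_design(n_A, n_B))
}
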