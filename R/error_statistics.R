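#' One-sample normal-mean test specification
#'
#' Defines a one-sided z-test of `H0: mu <= mu0` against `mu > mu0` for the
#' mean of a normal population with known standard deviation. This is the
#' frequentist test underlying the post-data severity function [sev()].
#'
#' @param mu0 Null value of the mean (measurement units).
#' @param sigma Known population standard deviation (same units, > 0).
#' @param n Sample size (>= 1).
#' @param alpha Type-I error rate, strictly between 0 and 1.
#' @param direction Direction of the alternative. Only `"greater"` is
#'   supported; the field exists so a lesser/two-sided extension is additive.
#'
#' @return An object of class `normal_test_spec` with fields `mu0`, `sigma`,
#'   `n`, `alpha`, `direction` and the derived standard error `se`.
#'
#' @examples
#' normal_test_spec(mu0 = 150, sigma = 10, n = 100, alpha = 0.025)
#' @export
normal_test_spec <- function(mu0, sigma, n, alpha, direction = "greater") {
  if (!is.finite(mu0)) stop("'mu0' must be finite")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  if (!is.finite(n) || n < 1 || n != round(n)) stop("'n' must be an integer >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  direction <- match.arg(direction, "greater")
  structure(
    list(mu0 = mu0, sigma = sigma, n = as.integer(n), alpha = alpha,
         direction = direction, se = sigma / sqrt(n)),
    class = "normal_test_spec"
  )
}

#' @export
print.normal_test_spec <- function(x, ...) {
  cat(sprintf(
    "One-sided normal-mean test: H0: mu <= %g vs mu > %g\n  sigma = %g, n = %d, se = %g, alpha = %g\n",
    x$mu0, x$mu0, x$sigma, x$n, x$se, x$alpha))
  invisible(x)
}

#' Rejection threshold of the one-sided normal-mean test
#'
#' The critical sample mean above which the test rejects `H0: mu <= mu0`:
#' `mu0 + z_(1 - alpha) * se`, with `se = sigma / sqrt(n)`. Observing a
#' sample mean at or above this cutoff is the "statistically significant"
#' event that a severity assessment presupposes.
#'
#' @param spec A [normal_test_spec()].
#' @return The critical mean (same units as `mu0`).
#' @examples
#' rejection_threshold(normal_test_spec(150, 10, 100, 0.025)) # 151.96
#' @export
rejection_threshold <- function(spec) {
  stopifnot(inherits(spec, "normal_test_spec"))
  spec$mu0 + stats::qnorm(1 - spec$alpha) * spec$se
}

#' Post-data severity of a claim about the mean
#'
#' Computes Mayo's severity for the claim `C: mu >= mu1` after observing a
#' sample mean `xbar` in the test defined by `spec`. Severity is evaluated at
#' the boundary point `mu = mu1` (the point in `C` closest to the null):
#' `SEV = P(Xbar <= xbar)` with `Xbar ~ Normal(mu1, se)` — the probability
#' that the test would have produced a result no larger than the one
#' observed, were the claim just false. High severity means the test had a
#' real chance of finding the claim wrong and did not.
#'
#' Note that the returned severity depends only on `mu1`, `xbar` and the
#' standard error: it is invariant to `mu0`, the test's notion of the normal
#' state of affairs.
#'
#' @param spec A [normal_test_spec()].
#' @param mu1 Claim threshold, `mu0 + delta`; the claim is `mu >= mu1`.
#' @param xbar Observed sample mean.
#' @return An object of class `sev_result`: a list with `sev` (the severity,
#'   in \[0, 1\]), `rejected` (did the observed mean clear the rejection
#'   threshold), and `critical_mean` (the threshold itself).
#' @examples
#' spec <- normal_test_spec(150, 10, 100, 0.025)
#' sev(spec, mu1 = 153, xbar = 152) # SEV = 0.159
#' @export
sev <- function(spec, mu1, xbar) {
  stopifnot(inherits(spec, "normal_test_spec"))
  if (!is.finite(mu1) || !is.finite(xbar))
    stop("'mu1' and 'xbar' must be finite")
  crit <- rejection_threshold(spec)
  structure(
    list(sev = stats::pnorm(xbar, mean = mu1, sd = spec$se),
         rejected = xbar >= crit,
         critical_mean = crit,
         mu1 = mu1, xbar = xbar),
    class = "sev_result"
  )
}

#' @export
print.sev_result <- function(x, ...) {
  cat(sprintf("SEV(mu >= %g | xbar = %g) = %.4f\n", x$mu1, x$xbar, x$sev))
  cat(sprintf("  test %s (critical mean %.4f)\n",
              if (x$rejected) "rejected H0" else "did not reject H0",
              x$critical_mean))
  invisible(x)
}

#' Severity as a function of the claim threshold
#'
#' Evaluates [sev()] over a grid of claim thresholds for a fixed observed
#' mean, e.g. to draw a severity curve. Severity is non-increasing in the
#' threshold: more ambitious claims pass less severely.
#'
#' @param spec A [normal_test_spec()].
#' @param xbar Observed sample mean.
#' @param mu1_grid Non-empty, ascending numeric vector of claim thresholds.
#' @return A data frame with columns `mu1` and `sev`.
#' @export
severity_curve <- function(spec, xbar, mu1_grid) {
  if (length(mu1_grid) == 0) stop("'mu1_grid' must be non-empty")
  if (is.unsorted(mu1_grid)) stop("'mu1_grid' must be sorted ascending")
  data.frame(
    mu1 = mu1_grid,
    sev = vapply(mu1_grid, function(m) sev(spec, m, xbar)$sev, numeric(1))
  )
}
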