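#' Load a scenario definition from a YAML or JSON file
#'
#' A scenario bundles a named analysis `kind` (`"sev"`, `"bf"`,
#' `"evidential_value"`, or `"bfda"`) with the parameters its module needs.
#' Bundled scenarios covering all the package's worked examples live under
#' `system.file("scenarios", package = "sevbf")`. Unknown keys are rejected
#' by name so a typo cannot silently change an analysis.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return An object of class `scenario`: `name`, `kind`, `parameters`.
#' @examples
#' p <- system.file("scenarios", "water_plant.yaml", package = "sevbf")
#' run_scenario(load_scenario(p))
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) config_error(sprintf("scenario file not found: %s", path))
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else
      yaml::read_yaml(path)
  }, error = function(e) {
    config_error(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  })
  if (is.null(raw) || !is.list(raw) || length(raw) == 0)
    config_error(sprintf("scenario file '%s' is empty", path))

  top_allowed <- c("name", "kind", "parameters")
  unknown <- setdiff(names(raw), top_allowed)
  if (length(unknown) > 0)
    config_error(sprintf("unknown scenario key(s): %s",
                         paste(unknown, collapse = ", ")))
  for (key in c("name", "kind", "parameters"))
    if (is.null(raw[[key]]))
      config_error(sprintf("scenario is missing required key '%s'", key))

  kinds <- c("sev", "bf", "evidential_value", "bfda")
  if (!raw$kind %in% kinds)
    config_error(sprintf("unknown scenario kind '%s' (expected one of: %s)",
                         raw$kind, paste(kinds, collapse = ", ")))

  # YAML 1.1 implicit typing turns an unquoted key `n:` into the boolean
  # FALSE; map it back rather than failing on a correct-looking file
  if (raw$kind == "sev" && "FALSE" %in% names(raw$parameters))
    names(raw$parameters)[names(raw$parameters) == "FALSE"] <- "n"

  allowed <- switch(raw$kind,
    sev = c("mu0", "sigma", "n", "alpha", "xbar", "mu1", "grid"),
    bf = c("label", "region_A", "region_B", "n_A", "n_B", "s_A", "s_B"),
    evidential_value = c("label", "region_A", "region_B", "n_A", "n_B",
                         "weights"),
    bfda = c("n_per_group", "effect_size_d", "prior_scale_r",
             "upper_threshold", "lower_threshold", "n_sims", "seed",
             "alternative"))
  unknown <- setdiff(names(raw$parameters), allowed)
  if (length(unknown) > 0)
    config_error(sprintf("unknown parameter key(s) for kind '%s': %s",
                         raw$kind, paste(unknown, collapse = ", ")))

  structure(list(name = raw$name, kind = raw$kind,
                 parameters = raw$parameters),
            class = "scenario")
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("sevbf_config_error", "error")))
}

#' Run a scenario and collect its results
#'
#' Dispatches a loaded [scenario][load_scenario()] to the module that owns
#' its kind and returns the results as a plain named list, ready for JSON
#' serialization. Validation errors in the parameters surface as
#' configuration errors carrying the scenario name.
#'
#' @param scenario A `scenario` object.
#' @return A named list of results; its contents depend on the kind:
#'   * `sev`: `sev`, `rejected`, `critical_mean` (plus `curve` if a grid was
#'     given);
#'   * `bf`: `bf`, `log_bf`, `prior_mass`, `posterior_mass`,
#'     `classification`;
#'   * `evidential_value`: `expectation`, `weights`, `per_outcome`;
#'   * `bfda`: the three rates, their standard errors, `n_sims`, `seed`.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  p <- scenario$parameters
  res <- tryCatch(
    switch(scenario$kind,
      sev = {
        spec <- normal_test_spec(p$mu0, p$sigma, p$n, p$alpha)
        r <- sev(spec, p$mu1, p$xbar)
        out <- list(sev = r$sev, rejected = r$rejected,
                    critical_mean = r$critical_mean)
        if (!is.null(p$grid))
          out$curve <- severity_curve(spec, p$xbar,
                                      seq(p$grid[1], p$grid[2], by = p$grid[3]))
        out
      },
      bf = {
        h <- interval_hypothesis(unlist(p$region_A), unlist(p$region_B),
                                 p$label %||% "H")
        y <- binomial_outcome(p$s_A, p$s_B, binomial_design(p$n_A, p$n_B))
        r <- bf_vs_encompassing(h, y)
        list(bf = r$bf, log_bf = r$log_bf, prior_mass = r$prior_mass,
             posterior_mass = r$posterior_mass,
             classification = classify_bf(r$bf))
      },
      evidential_value = {
        h <- interval_hypothesis(unlist(p$region_A), unlist(p$region_B),
                                 p$label %||% "H")
        w <- if (is.null(p$weights)) c(0.5, 0.5) else unlist(p$weights)
        r <- expected_abs_log_bf(h, binomial_design(p$n_A, p$n_B), w)
        list(expectation = r$expectation, weights = r$weights,
             per_outcome = r$per_outcome)
      },
      bfda = {
        spec <- bfda_spec(
          p$n_per_group, p$effect_size_d,
          prior_scale_r = p$prior_scale_r %||% sqrt(2) / 2,
          upper_threshold = p$upper_threshold %||% 3,
          lower_threshold = p$lower_threshold %||% (1 / 3),
          n_sims = p$n_sims %||% 10000,
          seed = p$seed,
          alternative = p$alternative %||% "greater")
        r <- simulate_bfda(spec)
        list(rate_evidence_H1 = r$rate_evidence_H1,
             rate_inconclusive = r$rate_inconclusive,
             rate_misleading_H0 = r$rate_misleading_H0,
             mc_standard_errors = as.list(r$mc_standard_errors),
             n_sims = spec$n_sims, seed = spec$seed)
      }),
    error = function(e) {
      if (inherits(e, "sevbf_config_error") ||
          inherits(e, "sevbf_numerical_error")) stop(e)
      config_error(sprintf("scenario '%s': %s",
                           scenario$name, conditionMessage(e)))
    })
  res$scenario <- scenario$name
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
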