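#' Load and validate a model configuration
#'
#' The configuration is a YAML file with sections `settings`, `patient`,
#' `strategies` (exactly two, one `role: intervention` and one
#' `role: comparator`, each with `curves`, `regimen`, `ae`), `costs`,
#' `utilities`, `disutilities`, `psa` and `parameters` (the sensitivity
#' specifications). Missing optional keys are filled with defaults and
#' reported via a message; structural problems raise errors naming the
#' offending key.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list of class `cea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  config <- yaml::read_yaml(path)
  validate_config(config)
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
validate_config <- function(config) {
  fail <- function(key, msg) {
    stop(sprintf("config key '%s': %s", key, msg), call. = FALSE)
  }
  need <- function(key) {
    if (is.null(get_config_value(config, key, missing_ok = TRUE))) {
      fail(key, "missing required key")
    }
  }
  for (k in c("settings", "strategies", "costs", "utilities", "patient")) need(k)

  defaults <- list(
    `settings.cycle_days` = 21,
    `settings.horizon_cycles` = 174,
    `settings.discount_rate` = 0.05,
    `settings.wtp` = 38224,
    `settings.background_mortality_annual` = 0.002,
    `settings.half_cycle_correction` = FALSE,
    `settings.ae_disutility_scope` = "intervention",
    `costs.supportive_gate` = "pfs",
    `costs.follow_up_gate` = "pfs_pd",
    `psa.n_iterations` = 1000,
    `psa.seed` = 20250101,
    `psa.include_survival_uncertainty` = TRUE,
    `psa.trial_cutoff_months` = 44,
    `psa.censor_rate_per_month` = 0.006
  )
  for (key in names(defaults)) {
    if (is.null(get_config_value(config, key, missing_ok = TRUE))) {
      config <- set_config_value(config, key, defaults[[key]])
      message(sprintf("config: '%s' not set, using default %s",
                      key, format(defaults[[key]])))
    }
  }

  s <- config$settings
  if (s$discount_rate < 0) fail("settings.discount_rate", "must be >= 0")
  for (k in c("cycle_days", "horizon_cycles", "wtp")) {
    if (s[[k]] <= 0) fail(paste0("settings.", k), "must be positive")
  }
  if (s$background_mortality_annual < 0 || s$background_mortality_annual > 1) {
    fail("settings.background_mortality_annual", "must lie in [0, 1]")
  }

  roles <- vapply(config$strategies, function(x) x$role %||% "", character(1))
  if (length(config$strategies) != 2 ||
      !setequal(roles, c("intervention", "comparator"))) {
    fail("strategies",
         "exactly two strategies with roles 'intervention' and 'comparator'")
  }
  for (nm in names(config$strategies)) {
    st <- config$strategies[[nm]]
    for (ep in c("pfs", "os")) {
      cv <- st$curves[[ep]]
      if (is.null(cv) || is.null(cv$family)) {
        fail(sprintf("strategies.%s.curves.%s", nm, ep), "missing curve")
      }
      # constructor validates family/parameters
      strategy_curve(st, ep)
    }
    if (is.null(st$regimen)) fail(sprintf("strategies.%s.regimen", nm),
                                  "missing regimen")
    for (a in names(st$ae)) {
      if (st$ae[[a]] < 0 || st$ae[[a]] > 1) {
        fail(sprintf("strategies.%s.ae.%s", nm, a),
             "incidence must lie in [0, 1]")
      }
    }
  }
  for (u in c("pfs", "pd")) {
    if (config$utilities[[u]] < 0 || config$utilities[[u]] > 1) {
      fail(paste0("utilities.", u), "must lie in [0, 1]")
    }
  }
  prices <- unlist(config$costs$drug_price_per_100mg)
  if (any(prices < 0)) fail("costs.drug_price_per_100mg", "must be >= 0")

  for (i in seq_along(config$parameters)) {
    p <- config$parameters[[i]]
    for (k in c("id", "path", "base", "lower", "upper", "dist")) {
      if (is.null(p[[k]])) {
        fail(sprintf("parameters[%d].%s", i, k), "missing field")
      }
    }
    if (is.null(get_config_value(config, p$path, missing_ok = TRUE))) {
      fail(sprintf("parameters[%d].path", i),
           sprintf("unresolvable path '%s'", p$path))
    }
    if (p$lower > p$upper) {
      fail(sprintf("parameters[%d]", i), "lower bound exceeds upper bound")
    }
    if (p$base < p$lower || p$base > p$upper) {
      warning(sprintf(
        "parameter '%s': base %g outside [%g, %g] (flagged, not fixed)",
        p$id, p$base, p$lower, p$upper), call. = FALSE)
    }
    match.arg(p$dist, c("gamma", "beta", "fixed"))
  }
  class(config) <- c("cea_config", "list")
  config
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The bundled base-case configuration (CPS >= 10 subgroup)
#'
#' First-line pembrolizumab + chemotherapy vs placebo + chemotherapy in
#' advanced triple-negative breast cancer with PD-L1 combined positive
#' score >= 10, from the Chinese healthcare-system perspective (2024 US$).
#'
#' @return A validated `cea_config`.
#' @export
cps10_config <- function() {
  suppressMessages(load_config(
    system.file("extdata", "cps10_base.yaml", package = "tnbcCEA",
                mustWork = TRUE)))
}

#' Navigate a configuration by dotted path
#'
#' `"costs.drug_price_per_100mg.pembrolizumab"` indexes
#' `config$costs$drug_price_per_100mg$pembrolizumab`. Used by the
#' sensitivity analyses to perturb single inputs.
#'
#' @param config Configuration list.
#' @param path Dotted key path.
#' @param missing_ok Return NULL instead of erroring when absent.
#' @return The value at the path.
#' @export
get_config_value <- function(config, path, missing_ok = FALSE) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    node <- node[[k]]
    if (is.null(node)) {
      if (missing_ok) return(NULL)
      stop(sprintf("config path '%s' not found", path), call. = FALSE)
    }
  }
  node
}

#' @rdname get_config_value
#' @param value Replacement value.
#' @export
set_config_value <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config[[keys]] <- value
  config
}
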