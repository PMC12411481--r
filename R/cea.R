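#' Build the survival model of one strategy endpoint
#'
#' @param strategy One entry of `config$strategies`.
#' @param endpoint `"pfs"` or `"os"`.
#' @return A [surv_model()].
#' @export
strategy_curve <- function(strategy, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  cv <- strategy$curves[[endpoint]]
  pars <- cv[setdiff(names(cv), "family")]
  surv_model_from_params(cv$family,
                         unlist(pars)[surv_param_names(cv$family)])
}

#' Run the two-arm cost-effectiveness model
#'
#' Runs the Markov cohort trace for both strategies from their fitted
#' PFS/OS curves, accumulates discounted costs, life-years and QALYs, and
#' computes the incremental comparison (intervention vs comparator).
#'
#' @param config A `cea_config` (see [load_config()], [cps10_config()]).
#' @return A `cea_result`: list with
#'   `strategies` (tibble: strategy, role, cost, life_years, qalys),
#'   `incremental` (list from [icer()]),
#'   `results` (per-strategy `econ_result`s, with cost components),
#'   `traces` (per-strategy cohort traces), and `wtp`.
#' @examples
#' \donttest{
#' res <- run_cea(cps10_config())
#' res$incremental$icer
#' }
#' @export
run_cea <- function(config) {
  if (!inherits(config, "cea_config")) config <- validate_config(config)
  s <- config$settings
  roles <- vapply(config$strategies, `[[`, character(1), "role")
  results <- list(); traces <- list()
  scope <- s$ae_disutility_scope %||% "intervention"
  for (nm in names(config$strategies)) {
    st <- config$strategies[[nm]]
    trace <- run_cohort(
      S_pfs = strategy_curve(st, "pfs"),
      S_os = strategy_curve(st, "os"),
      mortality = s$background_mortality_annual,
      horizon = s$horizon_cycles,
      cycle_days = s$cycle_days)
    apply_dis <- switch(scope,
      intervention = identical(st$role, "intervention"),
      per_arm = TRUE,
      stop("ae_disutility_scope must be 'intervention' or 'per_arm'",
           call. = FALSE))
    econ <- accumulate_outcomes(
      trace, regimen = st$regimen, costs = config$costs,
      utilities = config$utilities,
      ae = list(incidence = st$ae, disutility = config$disutilities),
      settings = s, patient = config$patient,
      apply_ae_disutility = apply_dis)
    results[[nm]] <- econ
    traces[[nm]] <- trace
  }
  int_nm <- names(roles)[roles == "intervention"]
  cmp_nm <- names(roles)[roles == "comparator"]
  inc <- icer(results[[int_nm]], results[[cmp_nm]])
  structure(list(
    strategies = tibble::tibble(
      strategy = names(results),
      role = unname(roles[names(results)]),
      cost = vapply(results, `[[`, numeric(1), "cost"),
      life_years = vapply(results, `[[`, numeric(1), "life_years"),
      qalys = vapply(results, `[[`, numeric(1), "qalys")),
    incremental = inc,
    results = results,
    traces = traces,
    intervention = int_nm,
    comparator = cmp_nm,
    wtp = s$wtp
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Two-arm Markov cohort cost-effectiveness model\n")
  print(x$strategies)
  inc <- x$incremental
  cat(sprintf("\nIncremental cost:  $%.2f\nIncremental QALYs: %.4f\n",
              inc$delta_cost, inc$delta_qaly))
  if (inc$dominance == "none") {
    cat(sprintf("ICER:              $%.2f per QALY (WTP $%s)\n",
                inc$icer, format(x$wtp, big.mark = ",")))
  } else {
    cat(sprintf("Dominance flag:    %s\n", inc$dominance))
  }
  invisible(x)
}

#' Export a cohort trace with per-cycle discounted cost and QALY columns
#'
#' @param result A `cea_result`.
#' @param strategy Strategy name.
#' @return The trace tibble of that strategy.
#' @export
cea_trace <- function(result, strategy) {
  stopifnot(inherits(result, "cea_result"))
  result$traces[[strategy]]
}
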